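#' Build nested HD/MD/LD marker panels
#'
#' Samples `hd_per_chromosome` markers per chromosome from the segregating
#' non-QTN sites, then the MD panel as a random `md_fraction` of HD and the
#' LD panel as a random `ld_fraction / md_fraction` share of MD, so that
#' LD is a subset of MD is a subset of HD and both lower densities are fixed
#' fractions of HD (0.30 and 0.003 reproduce missing rates of 70% and 99.7%
#' at any scale). Counts are allocated per chromosome, so the proportional-
#' per-chromosome assignment holds exactly.
#'
#' @param flat flattened pool (see [flatten_pool()]).
#' @param hd_per_chromosome HD markers per chromosome.
#' @param md_fraction MD panel size as a fraction of HD.
#' @param ld_fraction LD panel size as a fraction of HD.
#' @param qtn_idx global site indices reserved for QTNs (excluded from all
#'   panels).
#' @param seed integer seed.
#' @return object of class `marker_panel`: sorted global index vectors
#'   `hd`, `md`, `ld` and the fractions.
#' @export
build_panels <- function(flat, hd_per_chromosome, md_fraction = 0.30,
                         ld_fraction = 0.003, qtn_idx = integer(0),
                         seed = NULL) {
  stopifnot(ld_fraction <= md_fraction, md_fraction <= 1)
  .seed_if(seed)
  md_per_chr <- max(1L, round(md_fraction * hd_per_chromosome))
  ld_per_chr <- max(1L, round(ld_fraction * hd_per_chromosome))
  hd <- md <- ld <- integer(0)
  for (cc in sort(unique(flat$site_chr))) {
    avail <- setdiff(which(flat$site_chr == cc), qtn_idx)
    if (length(avail) < hd_per_chromosome) {
      stop(sprintf(paste0("build_panels: chromosome %d has %d non-QTN ",
                          "segregating sites, %d HD markers requested"),
                   cc, length(avail), hd_per_chromosome))
    }
    hd_c <- sort(sample(avail, hd_per_chromosome))
    md_c <- sort(sample(hd_c, md_per_chr))
    ld_c <- sort(sample(md_c, ld_per_chr))
    hd <- c(hd, hd_c); md <- c(md, md_c); ld <- c(ld, ld_c)
  }
  panel <- list(hd = hd, md = md, ld = ld,
                hd_per_chromosome = as.integer(hd_per_chromosome),
                md_fraction = md_fraction, ld_fraction = ld_fraction)
  class(panel) <- "marker_panel"
  panel
}

#' Missing rate of a lower-density panel relative to HD
#'
#' Fraction of HD markers not covered by the given platform.
#'
#' @param panel a `marker_panel`.
#' @param platform `"MD"` or `"LD"`.
#' @return missing rate in \[0, 1\].
#' @export
panel_missing_rate <- function(panel, platform = c("MD", "LD")) {
  platform <- match.arg(platform)
  sub <- if (platform == "MD") panel$md else panel$ld
  1 - length(sub) / length(panel$hd)
}

# Table-1 platform assignment per role for every scenario
.scenario_table <- function() {
  rbind(
    data.frame(scenario = "S1", grand_dams = "HD", grand_sires = "HD",
               dams = "HD", sires = "HD", progeny = "MD",
               progeny_split = 1.0, whole_genome = FALSE,
               female_ancestors_in_G = TRUE),
    data.frame(scenario = "S2", grand_dams = "HD", grand_sires = "HD",
               dams = "HD", sires = "HD", progeny = "LD",
               progeny_split = 1.0, whole_genome = FALSE,
               female_ancestors_in_G = TRUE),
    data.frame(scenario = "S3", grand_dams = "MD", grand_sires = "HD",
               dams = "HD", sires = "HD", progeny = "LD",
               progeny_split = 0.5, whole_genome = FALSE,
               female_ancestors_in_G = FALSE),
    data.frame(scenario = "S3_A", grand_dams = "MD", grand_sires = "HD",
               dams = "HD", sires = "HD", progeny = "LD",
               progeny_split = 0.5, whole_genome = TRUE,
               female_ancestors_in_G = FALSE),
    data.frame(scenario = "S4", grand_dams = "MD", grand_sires = "HD",
               dams = "MD", sires = "HD", progeny = "LD",
               progeny_split = 1.0, whole_genome = FALSE,
               female_ancestors_in_G = FALSE),
    data.frame(scenario = "S5", grand_dams = "LD", grand_sires = "HD",
               dams = "LD", sires = "HD", progeny = "LD",
               progeny_split = 1.0, whole_genome = FALSE,
               female_ancestors_in_G = FALSE),
    data.frame(scenario = "S6", grand_dams = "NG", grand_sires = "HD",
               dams = "MD", sires = "HD", progeny = "LD",
               progeny_split = 1.0, whole_genome = FALSE,
               female_ancestors_in_G = FALSE),
    data.frame(scenario = "S7", grand_dams = "NG", grand_sires = "HD",
               dams = "NG", sires = "HD", progeny = "LD",
               progeny_split = 1.0, whole_genome = FALSE,
               female_ancestors_in_G = FALSE),
    data.frame(scenario = "BLUP", grand_dams = "NG", grand_sires = "NG",
               dams = "NG", sires = "NG", progeny = "NG",
               progeny_split = 1.0, whole_genome = FALSE,
               female_ancestors_in_G = FALSE))
}

#' Genotyping strategy of one scenario
#'
#' Returns the per-role platform assignment (grand-dams, grand-sires, dams,
#' sires, progeny) of a scenario: S1-S7 and S3_A are the imputation
#' strategies (grand-sires and sires always HD; only candidate does are
#' genotyped in the progeny generation), `BLUP` is the pedigree-only control.
#'
#' @param scenario_id one of "S1".."S7", "S3_A", "BLUP".
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(scenario_id) {
  tab <- .scenario_table()
  r <- tab[tab$scenario == scenario_id, ]
  if (nrow(r) != 1L) {
    stop("scenario_spec: unknown scenario id '", scenario_id, "' (use ",
         paste(tab$scenario, collapse = ", "), ")")
  }
  spec <- as.list(r)
  class(spec) <- "scenario_spec"
  spec
}

#' All scenario identifiers
#' @return character vector of the supported scenario ids.
#' @export
scenario_ids <- function() .scenario_table()$scenario

#' Genotyping cost table
#'
#' Per-96-chip platform prices and the implied per-animal genotyping prices.
#'
#' @param platform_price named platform prices in EUR (per 96-chip platform).
#' @param chips_per_platform chips ("BeadChips") per platform.
#' @return object of class `cost_table` with `per_animal` prices (EUR),
#'   non-genotyped animals costing zero.
#' @export
cost_table <- function(platform_price = c(HD = 9600, MD = 4800, LD = 1056),
                       chips_per_platform = 96) {
  per_animal <- c(platform_price / chips_per_platform, NG = 0)
  ct <- list(platform_price = platform_price,
             chips_per_platform = chips_per_platform,
             per_animal = per_animal)
  class(ct) <- "cost_table"
  ct
}

#' Genotyping cost of a scenario
#'
#' Sums per-animal platform prices over the genotyped animals of the last
#' three generations; non-genotyped roles contribute nothing and a
#' half-genotyped progeny counts at the genotyped fraction.
#'
#' @param spec a `scenario_spec` (or scenario id).
#' @param role_counts animals per role; defaults to the full-scale layout
#'   (150 grand-dams, 35 grand-sires, 150 dams, 35 sires, 1500 candidate
#'   does).
#' @param costs a [cost_table()].
#' @return total cost in EUR.
#' @export
scenario_cost <- function(spec,
                          role_counts = c(grand_dams = 150, grand_sires = 35,
                                          dams = 150, sires = 35,
                                          progeny = 1500),
                          costs = cost_table()) {
  if (is.character(spec)) spec <- scenario_spec(spec)
  stopifnot(inherits(spec, "scenario_spec"))
  roles <- c("grand_dams", "grand_sires", "dams", "sires", "progeny")
  total <- 0
  for (r in roles) {
    n <- role_counts[[r]]
    if (r == "progeny") n <- n * spec$progeny_split
    total <- total + n * costs$per_animal[[spec[[r]]]]
  }
  total
}

#' Apply a scenario's genotyping mask
#'
#' Resolves the Table-1 roles from the pedigree (grand-parental generation:
#' all does and the sires actually used; parental generation: likewise;
#' progeny generation: candidate does only) and returns the masked genotype
#' matrix: each animal's visible markers are its platform's markers, all
#' others NA; non-genotyped animals are all-NA. In the half-genotyped
#' scenarios a random half of the candidate does is genotyped at LD — the
#' split depends only on the seed, so the plain and whole-genome variants of
#' the scenario share it within a replicate.
#'
#' @param spec a `scenario_spec` (or scenario id).
#' @param ped pedigree data.frame from [run_program()].
#' @param panel a `marker_panel`.
#' @param true_dosage function `(ids, cols)` returning true dosages, e.g.
#'   `sim$get_dosage`.
#' @param seed seed for the half-progeny split (replicate stream).
#' @return list: `geno` (integer matrix animals x HD markers, NA = missing),
#'   `roles` (data.frame id, role, platform), `hd_idx` (global site indices
#'   of the columns).
#' @export
apply_scenario <- function(spec, ped, panel, true_dosage, seed = NULL) {
  if (is.character(spec)) spec <- scenario_spec(spec)
  stopifnot(inherits(spec, "scenario_spec"))
  gens <- sort(unique(ped$generation))
  g_prog <- max(gens)
  roles <- .resolve_roles(ped, g_prog)
  # candidate does only; half of them in the split scenarios
  progeny_ids <- roles$id[roles$role == "progeny"]
  genotyped_progeny <- progeny_ids
  if (spec$progeny_split < 1) {
    .seed_if(seed)
    k <- round(length(progeny_ids) * spec$progeny_split)
    genotyped_progeny <- sort(sample(progeny_ids, k))
  }
  platform_of <- function(i) {
    r <- roles$role[i]
    p <- spec[[r]]
    if (r == "progeny" && !(roles$id[i] %in% genotyped_progeny)) p <- "NG"
    p
  }
  roles$platform <- vapply(seq_len(nrow(roles)), platform_of, character(1))
  hd_idx <- panel$hd
  col_of <- match(hd_idx, hd_idx)  # identity; columns are the HD markers
  geno <- matrix(NA_integer_, nrow(roles), length(hd_idx),
                 dimnames = list(roles$id, NULL))
  for (p in c("HD", "MD", "LD")) {
    ids <- roles$id[roles$platform == p]
    if (!length(ids)) next
    sites <- switch(p, HD = panel$hd, MD = panel$md, LD = panel$ld)
    cols <- match(sites, hd_idx)
    geno[as.character(ids), cols] <- true_dosage(ids, sites)
  }
  list(geno = geno, roles = roles, hd_idx = hd_idx)
}

# role assignment from generation structure: the last generation's does are
# the candidates; in the two parental generations all does plus the males
# that actually sired the next generation fill the Table-1 roles
.resolve_roles <- function(ped, g_prog) {
  used_sires <- function(g) sort(unique(ped$sire[ped$generation == g + 1L]))
  gd <- ped$id[ped$generation == g_prog - 2L & ped$sex == "F"]
  gs <- used_sires(g_prog - 2L)
  dm <- ped$id[ped$generation == g_prog - 1L & ped$sex == "F"]
  sr <- used_sires(g_prog - 1L)
  pr <- ped$id[ped$generation == g_prog & ped$sex == "F"]
  data.frame(
    id = c(gd, gs, dm, sr, pr),
    role = rep(c("grand_dams", "grand_sires", "dams", "sires", "progeny"),
               c(length(gd), length(gs), length(dm), length(sr), length(pr))))
}
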