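#' Pedigree-based phasing and imputation
#'
#' The imputation engine works on the HD marker grid of a masked scenario
#' matrix. Every genotyped animal is represented by a pair of soft haplotypes
#' (per-site probability that the allele is 1; the population allele
#' frequency where nothing is known). Animals are processed in pedigree
#' order: an animal without genotyped parents is phased from its own
#' genotype (homozygous sites are fully phased, heterozygous sites stay
#' uncertain), while an animal with genotyped parents is run through a
#' gamete-origin Viterbi that tracks which parental haplotype each stretch of
#' its genome was inherited from (joint 4-state path over its typed markers,
#' scored by dosage compatibility, one switch penalty per parental-haplotype
#' change). The chosen parental haplotypes both impute the animal's untyped
#' markers and phase its own pair of haplotypes for the next generation.
#'
#' @name imputation
NULL

# soft haplotypes of an animal without genotyped parents
.soft_haps_founder <- function(typed_cols, typed_dos, freq) {
  h1 <- h2 <- freq
  prov <- raw(length(freq))  # 0 unknown, 1 own genotype, 2 parental path
  h1[typed_cols] <- ifelse(typed_dos >= 2, 1, ifelse(typed_dos <= 0, 0, 0.5))
  h2[typed_cols] <- ifelse(typed_dos >= 2, 1, ifelse(typed_dos <= 0, 0, 0.5))
  prov[typed_cols] <- as.raw(1L)
  list(h1 = h1, h2 = h2, prov = prov)
}

# Mendelian consistency of an offspring/parent pair at shared typed sites:
# fraction of opposing homozygotes
.mendel_conflict <- function(off_dos, par_dos) {
  shared <- !is.na(off_dos) & !is.na(par_dos)
  if (!any(shared)) return(0)
  mean(abs(off_dos[shared] - par_dos[shared]) == 2)
}

#' Phase and impute a scenario's genotyped animals to HD
#'
#' Processes the masked genotype matrix generation-wise: ancestral
#' generations first (they serve as the phased reference), then the candidate
#' does. Candidates without genotypes are skipped unless the scenario imputes
#' whole genomes, in which case each receives a copy of its lowest-id
#' genotyped full sib's imputed genome (so non-genotyped full sibs carry
#' identical, duplicated genomes), falling back to the parent-average
#' expectation when no full sib was genotyped. A declared parent whose genotype conflicts
#' with the offspring at more than `conflict_threshold` of shared typed
#' markers (opposing homozygotes) is treated as unknown for that animal, with
#' a warning.
#'
#' @param spec a `scenario_spec` (or scenario id).
#' @param masked result of [apply_scenario()].
#' @param ped pedigree data.frame.
#' @param map_hd genetic map of the HD columns: list with `site_cM`,
#'   `chr_start`, `chr_len_cM` (see [flatten_pool()]; restricted to the HD
#'   marker columns).
#' @param freq allele frequencies of the HD columns (founder frequencies).
#' @param switch_penalty Viterbi cost per parental-haplotype switch between
#'   adjacent typed markers.
#' @param call_margin hard calls are emitted where the fractional dosage is
#'   within this margin of an integer.
#' @param conflict_threshold Mendelian-conflict rate above which a declared
#'   parent is ignored for phasing.
#' @return object of class `imputation_result`: `dosage` and `hard` matrices
#'   over the imputed candidates (rownames = ids), `typed_cols` per candidate
#'   platform, `candidates` data.frame (id, platform, imputed), and `phased`
#'   (soft haplotypes of the reference animals).
#' @export
run_imputation <- function(spec, masked, ped, map_hd, freq,
                           switch_penalty = 1, call_margin = 0.1,
                           conflict_threshold = 0.01) {
  if (is.character(spec)) spec <- scenario_spec(spec)
  geno <- masked$geno
  roles <- masked$roles
  S <- ncol(geno)
  chr0 <- as.integer(map_hd$chr_start) - 1L
  phased <- new.env(parent = emptyenv())
  prow <- match(roles$id, ped$id)
  gen_of <- ped$generation[prow]
  sire_of <- ped$sire[prow]
  dam_of <- ped$dam[prow]
  has_geno <- roles$platform != "NG"

  parent_haps <- function(pid, own_dos) {
    # soft haplotypes of a parent, or frequency fallback; drops the parent on
    # Mendelian conflict
    key <- as.character(pid)
    if (pid == 0L || !exists(key, envir = phased)) {
      return(list(h1 = freq, h2 = freq, known = FALSE))
    }
    ph <- get(key, envir = phased)
    if (!is.null(ph$dos)) {
      conf <- .mendel_conflict(own_dos, ph$dos)
      if (conf > conflict_threshold) {
        warning(sprintf(paste0("Mendelian conflict rate %.3f between animal ",
                               "and declared parent %d; parent ignored"),
                        conf, pid))
        return(list(h1 = freq, h2 = freq, known = FALSE))
      }
    }
    list(h1 = ph$h1, h2 = ph$h2, known = TRUE)
  }

  impute_one <- function(i) {
    own <- geno[i, ]
    typed_cols <- which(!is.na(own))
    typed_dos <- as.numeric(own[typed_cols])
    sh <- parent_haps(sire_of[i], own)
    dh <- parent_haps(dam_of[i], own)
    if (!sh$known && !dh$known) {
      ph <- .soft_haps_founder(typed_cols, typed_dos, freq)
      return(list(h1 = ph$h1, h2 = ph$h2, dos = own,
                  dosage = ph$h1 + ph$h2, duo = FALSE,
                  typed_cols = typed_cols, typed_dos = typed_dos))
    }
    duo <- .impute_duo(typed_cols - 1L, typed_dos, sh$h1, sh$h2, dh$h1,
                       dh$h2, map_hd$site_cM, chr0, switch_penalty)
    list(h1 = duo$pat, h2 = duo$mat, dos = own,
         dosage = duo$pat + duo$mat, duo = TRUE, state = duo$state,
         typed_cols = typed_cols, typed_dos = typed_dos,
         sh = sh, dh = dh)
  }

  ord <- order(gen_of, roles$id)
  is_prog <- roles$role == "progeny"
  cand_rows <- ord[is_prog[ord]]
  anc_rows <- ord[!is_prog[ord]]

  for (i in anc_rows) {
    if (!has_geno[i]) next
    assign(as.character(roles$id[i]), impute_one(i), envir = phased)
  }

  # long-range phasing via progeny: a duo-processed offspring's gamete-origin
  # path says which parental haplotype it inherited in each region; where the
  # offspring's transmitted allele is determined (it is homozygous, or the
  # other parent's contribution is phased), that allele is a vote for the
  # parent's haplotype at that marker. Votes resolve the heterozygous-site
  # phase of the top reference generation, then the duo pass is repeated with
  # the refined reference.
  votes <- new.env(parent = emptyenv())  # per parent: sum/cnt per haplotype
  add_votes <- function(pid, hap_idx, cols, alleles) {
    key <- as.character(pid)
    v <- if (exists(key, envir = votes)) get(key, envir = votes) else
      list(s1 = numeric(S), n1 = numeric(S), s2 = numeric(S),
           n2 = numeric(S))
    one <- hap_idx == 1L
    if (any(one)) {
      v$s1[cols[one]] <- v$s1[cols[one]] + alleles[one]
      v$n1[cols[one]] <- v$n1[cols[one]] + 1
    }
    if (any(!one)) {
      v$s2[cols[!one]] <- v$s2[cols[!one]] + alleles[!one]
      v$n2[cols[!one]] <- v$n2[cols[!one]] + 1
    }
    assign(key, v, envir = votes)
  }
  for (i in anc_rows) {
    if (!has_geno[i]) next
    o <- get(as.character(roles$id[i]), envir = phased)
    if (!isTRUE(o$duo)) next
    t <- o$typed_cols
    st <- o$state[t]
    ok <- st >= 0L
    t <- t[ok]; st <- st[ok]; d <- o$typed_dos[ok]
    sire_hap <- ifelse(bitwAnd(st, 2L) > 0L, 2L, 1L)
    dam_hap <- ifelse(bitwAnd(st, 1L) > 0L, 2L, 1L)
    s_all <- ifelse(sire_hap == 2L, o$sh$h2[t], o$sh$h1[t])
    d_all <- ifelse(dam_hap == 2L, o$dh$h2[t], o$dh$h1[t])
    # transmitted alleles, where determined
    s_vote <- ifelse(d == 0, 0, ifelse(d == 2, 1,
                                       ifelse(d_all %in% c(0, 1),
                                              1 - d_all, NA)))
    d_vote <- ifelse(d == 0, 0, ifelse(d == 2, 1,
                                       ifelse(s_all %in% c(0, 1),
                                              1 - s_all, NA)))
    if (o$sh$known && sire_of[i] > 0L) {
      k <- !is.na(s_vote)
      if (any(k)) add_votes(sire_of[i], sire_hap[k], t[k], s_vote[k])
    }
    if (o$dh$known && dam_of[i] > 0L) {
      k <- !is.na(d_vote)
      if (any(k)) add_votes(dam_of[i], dam_hap[k], t[k], d_vote[k])
    }
  }
  for (key in ls(votes)) {
    if (!exists(key, envir = phased)) next
    p <- get(key, envir = phased)
    v <- get(key, envir = votes)
    # refine only heterozygous or untyped markers; keep pair-sum consistency
    het <- rep(TRUE, S)
    het[p$typed_cols] <- p$typed_dos == 1
    u1 <- het & v$n1 > 0
    u2 <- het & v$n2 > 0
    p$h1[u1] <- v$s1[u1] / v$n1[u1]
    p$h2[u2] <- v$s2[u2] / v$n2[u2]
    typed_het <- p$typed_cols[p$typed_dos == 1]
    only1 <- intersect(which(u1 & !u2), typed_het)
    only2 <- intersect(which(u2 & !u1), typed_het)
    p$h2[only1] <- 1 - p$h1[only1]
    p$h1[only2] <- 1 - p$h2[only2]
    p$dosage <- ifelse(seq_len(S) %in% p$typed_cols, p$dosage,
                       p$h1 + p$h2)
    assign(key, p, envir = phased)
  }
  # second duo pass over the younger reference animals with the refined
  # reference
  for (i in anc_rows) {
    if (!has_geno[i]) next
    key <- as.character(roles$id[i])
    if (isTRUE(get(key, envir = phased)$duo)) {
      assign(key, impute_one(i), envir = phased)
    }
  }

  cand_ids <- roles$id[cand_rows]
  imputed <- matrix(NA_real_, length(cand_ids), S,
                    dimnames = list(cand_ids, NULL))
  status <- character(length(cand_ids))
  for (k in seq_along(cand_rows)) {
    i <- cand_rows[k]
    if (has_geno[i]) {
      imputed[k, ] <- impute_one(i)$dosage
      status[k] <- roles$platform[i]
    } else {
      status[k] <- if (isTRUE(spec$whole_genome)) "WG" else "NG"
    }
  }
  # whole-genome mode: a non-genotyped candidate receives a copy of its
  # lowest-id genotyped full sib's imputed genome (full sibs therefore end
  # up with identical, duplicated genomes); without a genotyped full sib it
  # falls back to the parent-average expectation
  wg_source <- rep(NA_integer_, length(cand_ids))
  if (isTRUE(spec$whole_genome)) {
    fam <- paste(sire_of[cand_rows], dam_of[cand_rows])
    for (k in which(status == "WG")) {
      sibs <- which(fam == fam[k] & status %in% c("LD", "MD", "HD"))
      if (length(sibs)) {
        src <- sibs[which.min(cand_ids[sibs])]
        imputed[k, ] <- imputed[src, ]
        wg_source[k] <- src
      } else {
        i <- cand_rows[k]
        imputed[k, ] <- impute_whole_genome(sire_of[i], dam_of[i], phased,
                                            freq)
      }
    }
  }
  keep <- status != "NG"
  dosage <- imputed[keep, , drop = FALSE]
  hard <- hard_calls(dosage, call_margin)
  # parent-average fallback rows: calls only where both parents are hard
  # homozygous
  wg <- which(status[keep] == "WG" & is.na(wg_source[keep]))
  if (length(wg)) {
    for (k in wg) {
      i <- cand_rows[keep][k]
      ds <- get(as.character(sire_of[i]), envir = phased)$dosage
      dd <- get(as.character(dam_of[i]), envir = phased)$dosage
      hom <- function(x) abs(x) <= call_margin | abs(x - 2) <= call_margin
      ok <- hom(ds) & hom(dd)
      hard[k, !ok] <- NA_integer_
    }
  }
  kept_rows <- cand_rows[keep]
  typed_cols <- lapply(kept_rows, function(i) which(!is.na(geno[i, ])))
  untyped_cols <- lapply(typed_cols, function(tc) setdiff(seq_len(S), tc))
  res <- list(dosage = dosage, hard = hard,
              typed_cols = typed_cols, untyped_cols = untyped_cols,
              candidates = data.frame(id = cand_ids, platform = status,
                                      imputed = keep),
              call_margin = call_margin,
              phased = phased)
  class(res) <- "imputation_result"
  res
}

#' Impute one animal from its parents' soft haplotypes
#'
#' Runs the gamete-origin Viterbi for a single animal: the joint 4-state path
#' (sire haplotype x dam haplotype) over the animal's typed markers, scored
#' by `|dosage - a_sire - a_dam|` with one switch penalty per
#' parental-haplotype change; untyped markers are filled from the inferred
#' parental haplotype (population frequency where the parent's phase is
#' unknown) and typed markers pass through unchanged.
#'
#' @param typed_cols 1-based column indices of the animal's typed markers.
#' @param typed_dos dosages at the typed markers.
#' @param sire_haps,dam_haps lists with soft haplotypes `h1`, `h2` over all
#'   markers; pass the allele-frequency vector for both haplotypes of an
#'   ungenotyped parent.
#' @param map_hd genetic map of the marker columns (`site_cM`, `chr_start`,
#'   `chr_len_cM`).
#' @param switch_penalty Viterbi switch penalty.
#' @return list with the inferred paternal/maternal gametes (`pat`, `mat`)
#'   and the fractional `dosage`.
#' @export
impute_individual <- function(typed_cols, typed_dos, sire_haps, dam_haps,
                              map_hd, switch_penalty = 1) {
  stopifnot(length(typed_cols) == length(typed_dos))
  duo <- .impute_duo(as.integer(typed_cols) - 1L, as.numeric(typed_dos),
                     sire_haps$h1, sire_haps$h2, dam_haps$h1, dam_haps$h2,
                     map_hd$site_cM, as.integer(map_hd$chr_start) - 1L,
                     switch_penalty)
  list(pat = duo$pat, mat = duo$mat, dosage = duo$pat + duo$mat)
}

#' Whole-genome imputation of a non-genotyped animal
#'
#' Expected dosage given two genotyped (imputed) parents:
#' `(dosage_sire + dosage_dam) / 2` per marker. Full sibs receive identical
#' vectors by construction.
#'
#' @param sire_id,dam_id parent ids.
#' @param phased environment of phased/imputed animals (from
#'   [run_imputation()]).
#' @param freq allele frequencies (fallback when a parent is missing raises
#'   an error instead: both parents must be genotyped).
#' @return numeric dosage vector.
#' @export
impute_whole_genome <- function(sire_id, dam_id, phased, freq) {
  ks <- as.character(sire_id); kd <- as.character(dam_id)
  if (sire_id == 0L || dam_id == 0L || !exists(ks, envir = phased) ||
      !exists(kd, envir = phased)) {
    stop("impute_whole_genome: both parents must be genotyped")
  }
  (get(ks, envir = phased)$dosage + get(kd, envir = phased)$dosage) / 2
}

#' Hard genotype calls from fractional dosages
#'
#' @param dosage numeric matrix in \[0, 2\].
#' @param margin calls are emitted within this distance of an integer.
#' @return integer matrix with NA where no call is made.
#' @export
hard_calls <- function(dosage, margin = 0.1) {
  r <- round(dosage)
  out <- ifelse(abs(dosage - r) <= margin, as.integer(r), NA_integer_)
  if (is.null(dim(out))) out <- matrix(out, nrow(dosage), ncol(dosage))
  dimnames(out) <- dimnames(dosage)
  out
}

#' Per-individual imputation accuracy
#'
#' Pearson correlation between the fractional imputed dosage and the true
#' dosage at each individual's untyped markers, computed one individual at a
#' time; individuals with zero variance in either vector at their untyped
#' markers are excluded from the mean and reported separately.
#'
#' @param true integer matrix of true dosages (same rows/columns as
#'   `imputed`).
#' @param imputed numeric matrix of imputed dosages.
#' @param untyped_cols list (per row) of untyped column indices, or a single
#'   vector shared by all rows.
#' @return list with `per_individual` (data.frame id, r, n_untyped), `mean`,
#'   `sd` and `n_excluded`.
#' @export
imputation_accuracy <- function(true, imputed, untyped_cols) {
  stopifnot(all(dim(true) == dim(imputed)))
  n <- nrow(imputed)
  if (!is.list(untyped_cols)) untyped_cols <- rep(list(untyped_cols), n)
  stopifnot(length(untyped_cols) == n)
  r <- vapply(seq_len(n), function(i) {
    u <- untyped_cols[[i]]
    if (length(u) == 0L) stop("imputation_accuracy: empty untyped set")
    a <- true[i, u]; b <- imputed[i, u]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, numeric(1))
  ids <- rownames(imputed)
  per <- data.frame(id = if (is.null(ids)) seq_len(n) else ids, r = r,
                    n_untyped = lengths(untyped_cols))
  list(per_individual = per, mean = mean(r, na.rm = TRUE),
       sd = stats::sd(r[!is.na(r)]), n_excluded = sum(is.na(r)))
}

#' Genotype yield at untyped markers
#'
#' Fraction of each individual's untyped markers that received a hard call.
#'
#' @param hard integer matrix of hard calls (NA = no call).
#' @param untyped_cols list (per row) of untyped column indices, or a single
#'   shared vector.
#' @return list with `per_individual` (data.frame id, yield) and `mean`.
#' @export
genotype_yield <- function(hard, untyped_cols) {
  n <- nrow(hard)
  if (!is.list(untyped_cols)) untyped_cols <- rep(list(untyped_cols), n)
  y <- vapply(seq_len(n), function(i) {
    u <- untyped_cols[[i]]
    if (length(u) == 0L) return(NA_real_)
    mean(!is.na(hard[i, u]))
  }, numeric(1))
  ids <- rownames(hard)
  list(per_individual = data.frame(id = if (is.null(ids)) seq_len(n) else
    ids, yield = y), mean = mean(y, na.rm = TRUE))
}
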