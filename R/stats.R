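#' Per-patient scan averages of metric records
#'
#' For each (patient, structure, arm) group, the arithmetic mean of DSC,
#' MSD and HD over that patient's evaluated scans. Failed records (empty
#' masks) are excluded from the means and counted in `n_failed`; a group
#' with no valid record is kept with missing means and flagged.
#'
#' @param records metric record data frame (see [compare_structures()]).
#' @return Data frame with one row per (patient, structure, arm):
#'   `dsc`, `msd`, `hd` means, `n_scans`, `n_failed`, `missing`.
#' @export
patient_scan_average <- function(records) {
  key <- interaction(records$patient_id, records$structure, records$arm,
                     drop = TRUE, sep = "\r")
  groups <- split(seq_len(nrow(records)), key)
  rows <- lapply(groups, function(ix) {
    r <- records[ix, ]
    ok <- r$status == "ok"
    data.frame(
      patient_id = r$patient_id[1], structure = r$structure[1],
      arm = r$arm[1],
      dsc = if (any(ok)) mean(r$dsc[ok]) else NA_real_,
      msd = if (any(ok)) mean(r$msd[ok]) else NA_real_,
      hd = if (any(ok)) mean(r$hd[ok]) else NA_real_,
      n_scans = sum(ok), n_failed = sum(!ok), missing = !any(ok),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Population median table over patient summaries
#'
#' The population value reported per (structure, arm, metric) is the median
#' over the patient-level scan averages, i.e. patients are first averaged
#' over their scans and the cohort median is taken across patients.
#'
#' @param summaries output of [patient_scan_average()].
#' @return Long data frame: `structure`, `arm`, `metric`, `median`,
#'   `n_patients`. Cells with no contributing patient are `NA`, not zero.
#' @export
population_median_table <- function(summaries) {
  metrics <- c("dsc", "msd", "hd")
  key <- interaction(summaries$structure, summaries$arm, drop = TRUE,
                     sep = "\r")
  groups <- split(seq_len(nrow(summaries)), key)
  rows <- lapply(groups, function(ix) {
    s <- summaries[ix, ]
    do.call(rbind, lapply(metrics, function(m) {
      v <- s[[m]][!is.na(s[[m]])]
      data.frame(structure = s$structure[1], arm = s$arm[1], metric = m,
                 median = if (length(v)) stats::median(v) else NA_real_,
                 n_patients = length(v), stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test of paired samples at the conventions used throughout the
#' package: zero differences are discarded before ranking (classic
#' Wilcoxon, not Pratt), midranks for tied absolute differences. In
#' `"exact"` mode (default for n <= 25 after zero removal) the null
#' distribution of the signed-rank statistic is the exact distribution over
#' all 2^n sign assignments of the observed midranks, computed by
#' convolution — identical to full enumeration, ties included. `"approximate"`
#' uses the normal approximation with tie-corrected variance.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param mode `"exact"` or `"approximate"`.
#' @return list with `statistic` (W+, the positive-rank sum), `p_value`,
#'   `n_effective` (pairs after zero removal), `all_zero` flag.
#' @export
wilcoxon_signed_rank <- function(x, y, mode = c("exact", "approximate")) {
  mode <- match.arg(mode)
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (!length(x)) stop("empty samples")
  d <- x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(statistic = 0, p_value = 1, n_effective = 0L,
                all_zero = TRUE))
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (mode == "exact" && n <= 25) {
    p <- exact_signed_rank_p(r, w)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sig2)  # continuity corrected
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(statistic = w, p_value = p, n_effective = n, all_zero = FALSE)
}

# Exact two-sided p-value of W+ = sum of positive-signed midranks under the
# 2^n equiprobable sign assignments. Midranks are multiples of 0.5, so
# doubling them gives integers; the distribution of the doubled statistic
# is built by convolving (delta_0 + delta_{2r})/2 over the ranks.
exact_signed_rank_p <- function(r, w) {
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  dist <- numeric(total + 1)  # index s+1 holds P(2*W+ = s)
  dist[1] <- 1
  for (rk in r2) {
    shifted <- c(numeric(rk), dist[seq_len(total + 1 - rk)])
    dist <- (dist + shifted) / 2
  }
  w2 <- as.integer(round(2 * w))
  p_le <- sum(dist[seq_len(w2 + 1)])
  p_ge <- sum(dist[(w2 + 1):(total + 1)])
  min(1, 2 * min(p_le, p_ge))
}

#' Pairwise arm comparison of patient summaries
#'
#' For every structure and metric: the population medians of both arms,
#' their difference `delta = median(A) - median(B)`, the median of the
#' patient-paired differences (an alternative delta definition, also
#' emitted), and the paired Wilcoxon p-value over patients present in both
#' arms. Patients missing either arm are dropped pairwise and counted.
#'
#' @param summaries output of [patient_scan_average()].
#' @param armA,armB arm labels, e.g. `"CT_MR"`, `"MR_MR"`, `"IOV"`.
#' @param mode Wilcoxon mode, see [wilcoxon_signed_rank()].
#' @param alpha significance level for the `significant` flag.
#' @return Data frame: `structure`, `metric`, medians per arm, `delta`
#'   (difference of medians), `median_paired_diff`, `p_value`,
#'   `significant`, `n_pairs`, `untestable`.
#' @export
paired_comparison <- function(summaries, armA, armB, mode = "exact",
                              alpha = 0.05) {
  sA <- summaries[summaries$arm == armA & !summaries$missing, ]
  sB <- summaries[summaries$arm == armB & !summaries$missing, ]
  structures <- sort(unique(c(sA$structure, sB$structure)))
  metrics <- c("dsc", "msd", "hd")
  rows <- list()
  for (st in structures) {
    a <- sA[sA$structure == st, ]
    b <- sB[sB$structure == st, ]
    common <- intersect(a$patient_id, b$patient_id)
    a <- a[match(common, a$patient_id), ]
    b <- b[match(common, b$patient_id), ]
    for (m in metrics) {
      va <- a[[m]]; vb <- b[[m]]
      ok <- !is.na(va) & !is.na(vb)
      va <- va[ok]; vb <- vb[ok]
      untestable <- length(va) < 2
      if (!untestable) {
        wt <- wilcoxon_signed_rank(va, vb, mode = mode)
        p <- wt$p_value
      } else p <- NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        structure = st, metric = m,
        median_A = if (length(va)) stats::median(va) else NA_real_,
        median_B = if (length(vb)) stats::median(vb) else NA_real_,
        delta = if (length(va)) stats::median(va) - stats::median(vb)
                else NA_real_,
        median_paired_diff = if (length(va)) stats::median(va - vb)
                             else NA_real_,
        p_value = p,
        significant = !is.na(p) & p < alpha,
        n_pairs = length(va), untestable = untestable,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "arms") <- c(A = armA, B = armB)
  out
}

#' Volume-ratio accuracy table
#'
#' One row per propagated record: the ratio of the planning ground-truth
#' volume (pCT for the CT-MR arm, pMR for the MR-MR arm) to the
#' ground-truth volume on the image of the day, joined with that record's
#' DSC and MSD. Large deviations of the ratio from 1 mark scan pairs whose
#' anatomical volume change the propagation had to absorb.
#'
#' @param records metric record data frame (propagated arms only are used).
#' @param gt_volumes data frame of ground-truth volumes: `patient_id`,
#'   `scan_id`, `structure`, `volume_cm3` (see [evaluate_cohort()]).
#' @return Data frame: identifiers, `ratio`, `dsc`, `msd`; records whose
#'   planning volume is unavailable are skipped and counted in the
#'   `n_skipped` attribute.
#' @export
volume_ratio_table <- function(records, gt_volumes) {
  prop <- records[records$arm %in% c("CT_MR", "MR_MR") &
                    records$status == "ok", ]
  planning_scan <- ifelse(prop$arm == "CT_MR", "pCT", "pMR")
  vkey <- paste(gt_volumes$patient_id, gt_volumes$scan_id,
                gt_volumes$structure, sep = "\r")
  vp <- gt_volumes$volume_cm3[match(
    paste(prop$patient_id, planning_scan, prop$structure, sep = "\r"), vkey)]
  vd <- gt_volumes$volume_cm3[match(
    paste(prop$patient_id, prop$scan_id, prop$structure, sep = "\r"), vkey)]
  keep <- !is.na(vp) & !is.na(vd) & vd > 0
  out <- data.frame(
    patient_id = prop$patient_id[keep], scan_id = prop$scan_id[keep],
    structure = prop$structure[keep], arm = prop$arm[keep],
    ratio = vp[keep] / vd[keep],
    dsc = prop$dsc[keep], msd = prop$msd[keep],
    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- sum(!keep)
  out
}

#' Planning CT vs planning MR volume comparison
#'
#' Per structure: median and range of the ground-truth volumes delineated
#' on the planning CT and on the planning MR, and the paired Wilcoxon
#' p-value of the CT-MR volume difference over patients. This quantifies
#' systematic modality delineation bias (e.g. the prostate delineated
#' larger on CT than on MR).
#'
#' @param gt_volumes ground-truth volume table (see [volume_ratio_table()]).
#' @param mode Wilcoxon mode.
#' @return Data frame per structure: medians, min/max per modality,
#'   `p_value`, `n_pairs`.
#' @export
planning_volume_comparison <- function(gt_volumes, mode = "exact") {
  ct <- gt_volumes[gt_volumes$scan_id == "pCT", ]
  mr <- gt_volumes[gt_volumes$scan_id == "pMR", ]
  structures <- sort(unique(c(ct$structure, mr$structure)))
  rows <- lapply(structures, function(st) {
    a <- ct[ct$structure == st, ]
    b <- mr[mr$structure == st, ]
    common <- intersect(a$patient_id, b$patient_id)
    va <- a$volume_cm3[match(common, a$patient_id)]
    vb <- b$volume_cm3[match(common, b$patient_id)]
    p <- if (length(common) >= 2)
      wilcoxon_signed_rank(va, vb, mode = mode)$p_value else NA_real_
    data.frame(structure = st,
               median_pCT = stats::median(va), min_pCT = min(va),
               max_pCT = max(va),
               median_pMR = stats::median(vb), min_pMR = min(vb),
               max_pMR = max(vb),
               p_value = p, n_pairs = length(common),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
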