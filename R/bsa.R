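# BSA-seq QTL detection: variant filtering, SNP index / delta(SNP-index),
# sliding-window scan, per-window permutation thresholds, region calling.

#' Filter a pooled variant table on depth and parental genotype criteria
#'
#' Applies the standard pre-mapping variant filters: records are dropped when
#' (1) either parent's depth is below `min_parent_depth`, (2) any pool's
#' depth is below `min_progeny_depth`, (3) the parents are not polymorphic
#' (identical homozygous genotypes), or (4) either parent is heterozygous.
#' Each removed record is tallied under the first criterion it fails, in
#' that order.
#'
#' @param tab a `pooled_variant_table` (or plain data frame) with per-pool
#'   `<pool>_ref_depth`/`<pool>_alt_depth` columns and, for the parent-based
#'   filters, `<parent>_depth` and `<parent>_gt` columns (genotypes coded
#'   `0/0`, `0/1`, `1/1`).
#' @param parents character vector of parent column prefixes; `NULL`
#'   disables the parent-based filters.
#' @param pools character vector of pool column prefixes; default: inferred
#'   from `*_alt_depth` columns not belonging to parents.
#' @param min_parent_depth,min_progeny_depth depth cutoffs (5 and 3).
#' @return the surviving records, with attribute `removal_tally` (named
#'   integer vector over `low_parent_depth`, `low_pool_depth`,
#'   `parents_monomorphic`, `parent_heterozygous`).
#' @export
filter_variants <- function(tab, parents = NULL, pools = NULL,
                            min_parent_depth = 5, min_progeny_depth = 3) {
  if (is.null(pools)) {
    pools <- sub("_alt_depth$", "",
                 grep("_alt_depth$", names(tab), value = TRUE))
    pools <- setdiff(pools, parents)
  }
  need <- c(paste0(pools, "_ref_depth"), paste0(pools, "_alt_depth"))
  if (!is.null(parents))
    need <- c(need, paste0(parents, "_depth"), paste0(parents, "_gt"))
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stopf("variant table is missing required columns: %s",
          paste(miss, collapse = ", "))

  n <- nrow(tab)
  if (n == 0L) {
    attr(tab, "removal_tally") <- c(low_parent_depth = 0L, low_pool_depth = 0L,
                                    parents_monomorphic = 0L,
                                    parent_heterozygous = 0L)
    return(tab)
  }
  low_parent <- rep(FALSE, n)
  het_parent <- rep(FALSE, n)
  mono <- rep(FALSE, n)
  if (!is.null(parents)) {
    pdepth <- matrix(sapply(parents, function(p) tab[[paste0(p, "_depth")]]),
                     nrow = n)
    low_parent <- apply(pdepth < min_parent_depth, 1, any)
    gts <- sapply(parents, function(p) tab[[paste0(p, "_gt")]])
    gts <- matrix(gts, nrow = n)
    het_parent <- apply(gts == "0/1" | gts == "1/0", 1, any)
    hom <- !het_parent
    mono <- hom & apply(gts, 1, function(g) length(unique(g)) == 1L)
  }
  pool_depth <- sapply(pools, function(p)
    tab[[paste0(p, "_ref_depth")]] + tab[[paste0(p, "_alt_depth")]])
  pool_depth <- matrix(pool_depth, nrow = n)
  low_pool <- apply(pool_depth < min_progeny_depth, 1, any)

  reason <- rep(NA_character_, n)
  reason[het_parent] <- "parent_heterozygous"
  reason[mono] <- "parents_monomorphic"
  reason[low_pool] <- "low_pool_depth"
  reason[low_parent] <- "low_parent_depth"
  keep <- is.na(reason)
  tally <- c(low_parent_depth = sum(reason == "low_parent_depth", na.rm = TRUE),
             low_pool_depth = sum(reason == "low_pool_depth", na.rm = TRUE),
             parents_monomorphic = sum(reason == "parents_monomorphic",
                                       na.rm = TRUE),
             parent_heterozygous = sum(reason == "parent_heterozygous",
                                       na.rm = TRUE))
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removal_tally") <- tally
  out
}

#' SNP index of a pool
#'
#' Fraction of reads carrying the alt (donor/B3-origin) allele:
#' `alt / (ref + alt)`. Undefined (NA) at zero total depth; such records
#' should be excluded upstream.
#'
#' @param ref_depth,alt_depth non-negative read counts (vectorized).
#' @return numeric vector in `[0, 1]` (NA where depth is zero).
#' @export
snp_index <- function(ref_depth, alt_depth) {
  if (any(ref_depth < 0, na.rm = TRUE) || any(alt_depth < 0, na.rm = TRUE))
    stopf("read depths must be non-negative")
  total <- ref_depth + alt_depth
  ifelse(total > 0, alt_depth / total, NA_real_)
}

#' Delta(SNP-index) between two pools
#'
#' Difference of the SNP indices, egusi pool minus the other pool; positive
#' values mean donor-allele enrichment in the egusi pool.
#'
#' @param index_egusi,index_other SNP indices of the two pools.
#' @return numeric vector in `[-1, 1]`.
#' @export
delta_index <- function(index_egusi, index_other) index_egusi - index_other

#' Sliding-window scan of per-SNP delta(SNP-index)
#'
#' Windows are anchored at multiples of `step` from position 0 and half-open
#' (`[start, start + window)`); the window statistic is the arithmetic mean
#' of delta over the SNPs inside. Windows with fewer than `min_snps` SNPs
#' are reported with `NA` mean and are never significant. Defaults follow
#' the 250-kb window / 5-kb step convention of QTL-seq style scans.
#'
#' @param snps data frame with columns `chrom`, `pos` (1-based, sorted
#'   within chromosome) and `delta`.
#' @param window,step window size and step in bp.
#' @param min_snps minimum SNPs for a window to be defined.
#' @return object of class `window_scan`: data frame with `chrom`, `start`,
#'   `end`, `n_snps`, `delta_mean` (plus `threshold`/`significant` once
#'   [add_thresholds()] has been run).
#' @export
window_scan <- function(snps, window = 250000, step = 5000, min_snps = 3) {
  if (window <= 0 || step <= 0) stopf("window and step must be positive")
  if (window %% step != 0)
    warning("`window` is not a multiple of `step`; region boundaries will not lie on a single grid",
            call. = FALSE)
  out <- lapply(split(snps, snps$chrom), function(d) {
    pos <- d$pos
    if (is.unsorted(pos)) {
      o <- order(pos)
      pos <- pos[o]
      d <- d[o, , drop = FALSE]
    }
    starts <- seq(0, floor(max(pos) / step) * step, by = step)
    lo <- findInterval(starts - 1, pos) + 1L
    hi <- findInterval(starts + window - 1, pos)
    n <- pmax(hi - lo + 1L, 0L)
    cs <- c(0, cumsum(d$delta))
    dm <- ifelse(n >= min_snps, (cs[hi + 1L] - cs[lo]) / n, NA_real_)
    data.frame(chrom = d$chrom[1], start = starts, end = starts + window,
               n_snps = n, delta_mean = dm, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  structure(out, class = c("window_scan", "data.frame"),
            window = window, step = step, min_snps = min_snps)
}

#' Per-window permutation threshold for |delta(SNP-index)|
#'
#' Monte-Carlo null for one window, conditioned on the observed per-SNP
#' depths. Each replicate redraws the composition of each pool once (the
#' same pooled plants underlie every SNP of a 250-kb window, so composition
#' noise is shared across its SNPs): under a BC1 design each of the `m`
#' plants carries 1 or 2 copies of the donor allele with probability 1/2
#' each; under an F2, 0/1/2 copies with probabilities 1/4, 1/2, 1/4. Read
#' counts are then drawn Binomial(observed depth, pool frequency) per SNP,
#' and the replicate's window-mean delta recorded. The threshold is the
#' empirical `confidence` quantile of |delta|; it is deterministic for a
#' fixed seed.
#'
#' @param depth_egusi,depth_other observed per-SNP total depths of the two
#'   pools in the window.
#' @param m_egusi,m_other number of plants in each pool.
#' @param design `"BC1"` or `"F2"`.
#' @param n_perm number of permutation replicates (1000).
#' @param confidence confidence level of the threshold (0.99).
#' @param seed integer seed.
#' @return the threshold (single non-negative number).
#' @export
permutation_threshold <- function(depth_egusi, depth_other, m_egusi = 20,
                                  m_other = 20, design = c("BC1", "F2"),
                                  n_perm = 1000, confidence = 0.99,
                                  seed = NULL) {
  design <- match.arg(design)
  if (n_perm < 100)
    warning("n_perm < 100: empirical quantile will be unstable", call. = FALSE)
  s <- length(depth_egusi)
  if (length(depth_other) != s) stopf("pool depth vectors differ in length")
  null_freq <- function(m, R) {
    if (design == "BC1") (m + stats::rbinom(R, m, 0.5)) / (2 * m)
    else stats::rbinom(R, 2 * m, 0.5) / (2 * m)
  }
  with_seed(seed, {
    fe <- null_freq(m_egusi, n_perm)
    fo <- null_freq(m_other, n_perm)
    de <- rep(depth_egusi, each = n_perm)
    do <- rep(depth_other, each = n_perm)
    ie <- stats::rbinom(n_perm * s, de, fe) / de
    io <- stats::rbinom(n_perm * s, do, fo) / do
    delta_bar <- rowMeans(matrix(ie - io, n_perm, s))
    unname(stats::quantile(abs(delta_bar), confidence, na.rm = TRUE))
  })
}

#' Attach permutation thresholds and significance flags to a window scan
#'
#' Runs [permutation_threshold()] for every defined window, using the
#' observed depths of the SNPs inside it, and flags windows whose
#' |mean delta| exceeds their threshold.
#'
#' @param scan a [window_scan()] result.
#' @param snps the per-SNP table used for the scan, additionally carrying
#'   `depth_egusi` and `depth_other` columns.
#' @param m_egusi,m_other,design,n_perm,confidence,seed passed to
#'   [permutation_threshold()]; each window gets a sub-seed derived from
#'   `seed`, so results are reproducible and independent of scan order.
#' @return the scan with `threshold` and `significant` columns filled.
#' @export
add_thresholds <- function(scan, snps, m_egusi = 20, m_other = 20,
                           design = "BC1", n_perm = 1000, confidence = 0.99,
                           seed = NULL) {
  window <- attr(scan, "window")
  scan$threshold <- NA_real_
  by_chrom <- split(seq_len(nrow(snps)), snps$chrom)
  for (w in which(!is.na(scan$delta_mean))) {
    idx <- by_chrom[[as.character(scan$chrom[w])]]
    pos <- snps$pos[idx]
    inside <- idx[pos >= scan$start[w] & pos < scan$start[w] + window]
    scan$threshold[w] <- permutation_threshold(
      snps$depth_egusi[inside], snps$depth_other[inside],
      m_egusi, m_other, design, n_perm, confidence,
      seed = child_seed(seed, w))
  }
  scan$significant <- !is.na(scan$delta_mean) &
    abs(scan$delta_mean) > scan$threshold
  scan
}

#' Call candidate QTL regions from a thresholded window scan
#'
#' Merges maximal runs of grid-consecutive significant windows per
#' chromosome into regions `[min start, max end]` and reports each region's
#' peak delta (the signed mean of largest magnitude) with its threshold.
#' Region boundaries inherit the step grid, i.e. they are multiples of the
#' scan step.
#'
#' @param scan a [window_scan()] with `significant` flags (see
#'   [add_thresholds()]).
#' @return data frame with columns `chrom`, `from_bp`, `to_bp`,
#'   `peak_delta`, `peak_threshold`, `n_windows`.
#' @export
call_regions <- function(scan) {
  if (is.null(scan$significant))
    stopf("scan has no significance flags; run add_thresholds() first")
  step <- attr(scan, "step")
  sig <- scan[scan$significant, , drop = FALSE]
  empty <- data.frame(chrom = character(), from_bp = numeric(),
                      to_bp = numeric(), peak_delta = numeric(),
                      peak_threshold = numeric(), n_windows = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(sig)) return(empty)
  out <- lapply(split(sig, sig$chrom, drop = TRUE), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    run <- cumsum(c(1, diff(d$start) > step))
    do.call(rbind, lapply(split(d, run), function(r) {
      peak <- which.max(abs(r$delta_mean))
      data.frame(chrom = r$chrom[1], from_bp = min(r$start),
                 to_bp = max(r$end), peak_delta = r$delta_mean[peak],
                 peak_threshold = r$threshold[peak], n_windows = nrow(r),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$from_bp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full BSA-seq scan from a pooled variant table
#'
#' Computes per-SNP indices and delta(SNP-index) for the two named pools
#' (records with zero depth in either pool are dropped), runs the sliding
#' window scan, attaches per-window permutation thresholds, and calls
#' candidate QTL regions.
#'
#' @param tab a `pooled_variant_table` (e.g. from
#'   [simulate_pooled_counts()] or [read_variants()]).
#' @param egusi_pool,other_pool pool column prefixes.
#' @param design,m_egusi,m_other,window,step,min_snps,n_perm,confidence,seed
#'   scan parameters; see [window_scan()] and [permutation_threshold()].
#' @return list of class `bsa_result` with elements `snps`, `windows`,
#'   `regions`.
#' @export
bsa_scan <- function(tab, egusi_pool = "egusi", other_pool = "non_egusi",
                     design = "BC1", m_egusi = 20, m_other = 20,
                     window = 250000, step = 5000, min_snps = 3,
                     n_perm = 1000, confidence = 0.99, seed = NULL) {
  re <- tab[[paste0(egusi_pool, "_ref_depth")]]
  ae <- tab[[paste0(egusi_pool, "_alt_depth")]]
  ro <- tab[[paste0(other_pool, "_ref_depth")]]
  ao <- tab[[paste0(other_pool, "_alt_depth")]]
  if (is.null(re) || is.null(ro))
    stopf("pool columns '%s'/'%s' not found in variant table",
          egusi_pool, other_pool)
  keep <- (re + ae) > 0 & (ro + ao) > 0
  snps <- data.frame(chrom = tab$chrom[keep], pos = tab$pos[keep],
                     delta = delta_index(snp_index(re, ae)[keep],
                                         snp_index(ro, ao)[keep]),
                     depth_egusi = (re + ae)[keep],
                     depth_other = (ro + ao)[keep],
                     stringsAsFactors = FALSE)
  scan <- window_scan(snps, window, step, min_snps)
  scan <- add_thresholds(scan, snps, m_egusi, m_other, design, n_perm,
                         confidence, seed)
  structure(list(snps = snps, windows = scan, regions = call_regions(scan)),
            class = "bsa_result")
}

#' @export
print.bsa_result <- function(x, ...) {
  cat(sprintf("BSA scan: %d SNPs, %d windows (%d defined), %d region(s)\n",
              nrow(x$snps), nrow(x$windows), sum(!is.na(x$windows$delta_mean)),
              nrow(x$regions)))
  if (nrow(x$regions)) print(x$regions)
  invisible(x)
}
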