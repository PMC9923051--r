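# Recombinant-driven fine-mapping: graphical genotypes, marker QC,
# breakpoint detection, phenotype-consistency constraints, interval
# intersection, cosegregation checks.

#' Graphical genotype of a mapping population
#'
#' Bundles an ordered marker panel, a genotype-call matrix and phenotypes.
#' Calls are coded `a` (homozygous recurrent parent), `h` (heterozygous),
#' `b` (homozygous donor) and `NA` (missing). Under the single-locus
#' recessive model with the recurrent parent homozygous recessive, the
#' causal genotype required by a phenotype is: `design = "BC1"`: egusi -> a,
#' non-egusi -> h; `design = "selfed"` (BC1F2/F2, heterozygote dominant):
#' egusi -> a, non-egusi -> h or b.
#'
#' @param markers data frame with at least `name`, `chrom`, `pos_bp`
#'   (optionally `type`, `enzyme`); reordered by position.
#' @param calls character matrix, individuals x markers (column names must
#'   match marker names), values in `a/h/b` or NA.
#' @param phenotype character vector per individual (`egusi`, `non_egusi`,
#'   or NA for unknown).
#' @param design `"BC1"` or `"selfed"`.
#' @return object of class `graphical_genotype`.
#' @export
graphical_genotype <- function(markers, calls, phenotype,
                               design = c("BC1", "selfed")) {
  design <- match.arg(design)
  if (anyDuplicated(markers$name)) stopf("marker names must be unique")
  o <- order(markers$chrom, markers$pos_bp)
  markers <- markers[o, , drop = FALSE]
  if (any(duplicated(markers[c("chrom", "pos_bp")])))
    stopf("marker positions must be strictly increasing within chromosomes")
  rownames(markers) <- NULL
  calls <- as.matrix(calls)
  if (is.null(colnames(calls)) || !setequal(colnames(calls), markers$name))
    stopf("call matrix columns must match the marker panel")
  calls <- calls[, markers$name, drop = FALSE]
  bad <- !(calls %in% c("a", "h", "b") | is.na(calls))
  if (any(bad)) stopf("invalid genotype call '%s'", calls[bad][1])
  if (length(phenotype) != nrow(calls))
    stopf("need one phenotype per individual")
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("ind%03d", seq_len(nrow(calls)))
  structure(list(markers = markers, calls = calls,
                 phenotype = as.character(phenotype), design = design),
            class = "graphical_genotype")
}

required_classes <- function(phenotype, design) {
  if (is.na(phenotype)) return(NULL)
  if (phenotype == "egusi") return("a")
  if (design == "BC1") "h" else c("h", "b")
}

#' Marker quality filter
#'
#' Drops markers with more than `max_missing` missing calls or with
#' significant segregation distortion (chi-square against the design ratio:
#' 1:1 a:h for BC1, 1:2:1 a:h:b for selfed generations; P <
#' `distortion_alpha`).
#'
#' @param gg a [graphical_genotype()].
#' @param max_missing maximum tolerated missing fraction (0.5).
#' @param distortion_alpha distortion test level (0.05).
#' @return the filtered `graphical_genotype`, with attribute `removed`
#'   (data frame of dropped markers and reasons).
#' @export
filter_markers <- function(gg, max_missing = 0.5, distortion_alpha = 0.05) {
  calls <- gg$calls
  reason <- rep(NA_character_, ncol(calls))
  for (j in seq_len(ncol(calls))) {
    cj <- calls[, j]
    if (mean(is.na(cj)) > max_missing) {
      reason[j] <- "excess_missing"
      next
    }
    counts <- if (gg$design == "BC1") {
      c(sum(cj == "a", na.rm = TRUE), sum(cj == "h", na.rm = TRUE))
    } else {
      c(sum(cj == "a", na.rm = TRUE), sum(cj == "h", na.rm = TRUE),
        sum(cj == "b", na.rm = TRUE))
    }
    ratio <- if (gg$design == "BC1") "1:1" else "1:2:1"
    if (sum(counts) > 0 &&
        chi_square_gof(counts, ratio)$p < distortion_alpha)
      reason[j] <- "segregation_distortion"
  }
  keep <- is.na(reason)
  if (!any(keep)) stopf("all markers removed by quality filters")
  removed <- data.frame(name = gg$markers$name[!keep],
                        reason = reason[!keep], stringsAsFactors = FALSE)
  out <- graphical_genotype(gg$markers[keep, , drop = FALSE],
                            calls[, keep, drop = FALSE], gg$phenotype,
                            gg$design)
  attr(out, "removed") <- removed
  out
}

#' Detect recombinant individuals and localize their breakpoints
#'
#' A breakpoint is declared between adjacent informative (non-missing)
#' markers whose genotype class changes; missing calls are transparent, so
#' a breakpoint is localized between the nearest informative markers on
#' either side. Individuals with at least one breakpoint are recombinant.
#'
#' @param gg a [graphical_genotype()].
#' @return list with `recombinant` (named logical), `breakpoints` (per
#'   individual, data frame of `chrom`, `left_marker`, `right_marker`) and
#'   `excluded` (ids with no informative call, dropped with a warning).
#' @export
detect_recombinants <- function(gg) {
  ids <- rownames(gg$calls)
  bps <- stats::setNames(vector("list", length(ids)), ids)
  excluded <- character()
  for (i in seq_along(ids)) {
    res <- list()
    any_inf <- FALSE
    for (cn in unique(gg$markers$chrom)) {
      jj <- which(gg$markers$chrom == cn)
      cj <- gg$calls[i, jj]
      inf <- which(!is.na(cj))
      any_inf <- any_inf || length(inf) > 0
      if (length(inf) < 2) next
      chg <- which(cj[inf][-1] != cj[inf][-length(inf)])
      if (length(chg))
        res[[as.character(cn)]] <- data.frame(
          chrom = cn,
          left_marker = gg$markers$name[jj[inf[chg]]],
          right_marker = gg$markers$name[jj[inf[chg + 1]]],
          stringsAsFactors = FALSE)
    }
    if (!any_inf) {
      excluded <- c(excluded, ids[i])
      bps[[i]] <- NULL
    } else {
      bps[[i]] <- if (length(res)) do.call(rbind, res) else
        data.frame(chrom = character(), left_marker = character(),
                   right_marker = character(), stringsAsFactors = FALSE)
      rownames(bps[[i]]) <- NULL
    }
  }
  if (length(excluded))
    warning(sprintf("excluded %d individual(s) with no informative call: %s",
                    length(excluded), paste(excluded, collapse = ", ")),
            call. = FALSE)
  keep <- setdiff(ids, excluded)
  list(recombinant = vapply(bps[keep], function(b) nrow(b) > 0, TRUE),
       breakpoints = bps[keep], excluded = excluded)
}

#' Genomic region allowed for the causal locus by one individual
#'
#' Under the single-locus recessive model, an individual's phenotype
#' dictates the genotype class the causal position must carry; every
#' maximal run of informative markers of that class, extended outward to
#' the positions of the nearest flanking inconsistent informative markers
#' (clamped to the panel extent), is allowed. Unknown phenotypes impose no
#' constraint (whole panel); an individual whose informative calls are all
#' inconsistent has an empty allowed set.
#'
#' @param gg a [graphical_genotype()] (single-chromosome panel).
#' @param individual row index or id.
#' @return data frame of allowed segments: `start_bp`, `end_bp`,
#'   `left_marker`, `right_marker` (zero rows = empty set).
#' @export
phenotype_constraint <- function(gg, individual) {
  mk <- gg$markers
  if (length(unique(mk$chrom)) != 1L)
    stopf("phenotype constraints need a single-chromosome panel")
  if (is.character(individual))
    individual <- match(individual, rownames(gg$calls))
  cj <- gg$calls[individual, ]
  req <- required_classes(gg$phenotype[individual], gg$design)
  whole <- data.frame(start_bp = mk$pos_bp[1], end_bp = mk$pos_bp[nrow(mk)],
                      left_marker = mk$name[1], right_marker = mk$name[nrow(mk)],
                      stringsAsFactors = FALSE)
  if (is.null(req)) return(whole)
  inf <- which(!is.na(cj))
  if (!length(inf)) return(whole)
  cons <- cj[inf] %in% req
  if (!any(cons)) return(whole[0, , drop = FALSE])
  runs <- rle(cons)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  segs <- lapply(which(runs$values), function(r) {
    # indices (into `inf`) of the flanking inconsistent markers, if any
    li <- if (starts[r] > 1L) inf[starts[r] - 1L] else NA_integer_
    ri <- if (ends[r] < length(inf)) inf[ends[r] + 1L] else NA_integer_
    lj <- if (is.na(li)) 1L else li
    rj <- if (is.na(ri)) nrow(mk) else ri
    data.frame(start_bp = mk$pos_bp[lj], end_bp = mk$pos_bp[rj],
               left_marker = mk$name[lj], right_marker = mk$name[rj],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, segs)
}

# intersect two closed-segment sets (data frames as above)
intersect_segments <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(a[0, , drop = FALSE])
  out <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    s <- max(a$start_bp[i], b$start_bp[j])
    e <- min(a$end_bp[i], b$end_bp[j])
    if (s <= e) {
      lm <- if (a$start_bp[i] >= b$start_bp[j]) a$left_marker[i] else
        b$left_marker[j]
      rm_ <- if (a$end_bp[i] <= b$end_bp[j]) a$right_marker[i] else
        b$right_marker[j]
      out[[length(out) + 1L]] <- data.frame(
        start_bp = s, end_bp = e, left_marker = lm, right_marker = rm_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(a[0, , drop = FALSE])
  res <- do.call(rbind, out)
  res[order(res$start_bp), , drop = FALSE]
}

#' A marker-flanked genomic interval
#'
#' @param chrom chromosome id/name.
#' @param start_bp,end_bp 1-based inclusive bounds (marker positions).
#' @param left_marker,right_marker flanking marker names.
#' @return object of class `genomic_interval` with `width_bp` and
#'   `width_kb` (one decimal).
#' @export
genomic_interval <- function(chrom, start_bp, end_bp, left_marker = NA,
                             right_marker = NA) {
  if (end_bp < start_bp) stopf("interval end before start")
  structure(list(chrom = chrom, start_bp = start_bp, end_bp = end_bp,
                 left_marker = left_marker, right_marker = right_marker,
                 width_bp = end_bp - start_bp,
                 width_kb = round((end_bp - start_bp) / 1000, 1)),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("%s:%s-%s (%s kb), flanked by %s / %s\n", x$chrom,
              format(x$start_bp, big.mark = ","),
              format(x$end_bp, big.mark = ","),
              format(x$width_kb, nsmall = 1), x$left_marker, x$right_marker))
  invisible(x)
}

#' Physical width between two markers
#'
#' @param left,right marker names (looked up in `markers`) or single-row
#'   data frames with `chrom` and `pos_bp`.
#' @param markers marker panel data frame, required when names are given.
#' @return list with `width_bp` and `width_kb` (rounded to one decimal).
#' @examples
#' panel <- data.frame(name = c("N6-25", "N6-43"), chrom = "Chr06",
#'                     pos_bp = c(7040484, 7056134))
#' interval_width("N6-25", "N6-43", panel)  # 15650 bp, 15.7 kb
#' @export
interval_width <- function(left, right, markers = NULL) {
  get1 <- function(m) {
    if (is.character(m)) {
      i <- match(m, markers$name)
      if (is.na(i)) stopf("marker '%s' not in panel", m)
      markers[i, , drop = FALSE]
    } else m
  }
  l <- get1(left); r <- get1(right)
  if (!identical(as.character(l$chrom), as.character(r$chrom)))
    stopf("markers lie on different chromosomes")
  if (l$pos_bp > r$pos_bp) stopf("left marker lies right of right marker")
  w <- r$pos_bp - l$pos_bp
  list(width_bp = w, width_kb = round(w / 1000, 1))
}

#' Narrow the causal interval from all recombinant constraints
#'
#' Intersects every individual's allowed set ([phenotype_constraint()]).
#' Individuals whose own allowed set is empty (genotype-phenotype
#' inconsistent, like a mis-phenotyped plant) are excluded from the
#' intersection and reported. The result is the maximal marker-flanked
#' interval containing every position consistent with all remaining
#' constraints.
#'
#' @param gg a [graphical_genotype()] (single-chromosome panel).
#' @return list of class `narrow_result`: `interval` (a
#'   [genomic_interval()]), `inconsistent` (ids), `n_recombinant`,
#'   `segments` (the intersection, possibly several segments).
#' @export
narrow_interval <- function(gg) {
  mk <- gg$markers
  if (length(unique(mk$chrom)) != 1L)
    stopf("narrow_interval needs a single-chromosome panel")
  ids <- rownames(gg$calls)
  allowed <- lapply(seq_along(ids), function(i) phenotype_constraint(gg, i))
  inconsistent <- ids[vapply(allowed, nrow, 0L) == 0L]
  use <- which(vapply(allowed, nrow, 0L) > 0L)
  if (!length(use)) stopf("no informative consistent individual")
  acc <- allowed[[use[1]]]
  for (i in use[-1]) {
    nxt <- intersect_segments(acc, allowed[[i]])
    if (!nrow(nxt)) {
      # locate a minimal conflicting pair for the error message
      for (j in use) {
        if (!nrow(intersect_segments(allowed[[j]], allowed[[i]])))
          stopf("constraints conflict: individuals %s and %s share no allowed region",
                ids[j], ids[i])
      }
      stopf("constraints conflict at individual %s", ids[i])
    }
    acc <- nxt
  }
  start <- min(acc$start_bp); end <- max(acc$end_bp)
  lm <- acc$left_marker[which.min(acc$start_bp)]
  rm_ <- acc$right_marker[which.max(acc$end_bp)]
  rec <- detect_recombinants(gg)
  structure(list(
    interval = genomic_interval(mk$chrom[1], start, end, lm, rm_),
    inconsistent = inconsistent,
    n_recombinant = sum(rec$recombinant),
    segments = acc), class = "narrow_result")
}

#' @export
print.narrow_result <- function(x, ...) {
  print(x$interval)
  cat(sprintf("%d recombinant individual(s); %d inconsistent excluded%s\n",
              x$n_recombinant, length(x$inconsistent),
              if (length(x$inconsistent))
                paste0(" (", paste(x$inconsistent, collapse = ", "), ")")
              else ""))
  invisible(x)
}

#' Does a marker cosegregate with the phenotype?
#'
#' A marker cosegregates when, for every individual with a scored call and
#' known phenotype, the call belongs to the genotype class the phenotype
#' requires under the single-locus model.
#'
#' @param gg a [graphical_genotype()].
#' @param marker marker name.
#' @return list with `cosegregates` (logical) and `mismatched` (ids).
#' @export
cosegregation_check <- function(gg, marker) {
  j <- match(marker, gg$markers$name)
  if (is.na(j)) stopf("marker '%s' not in panel", marker)
  cj <- gg$calls[, j]
  mism <- character()
  for (i in seq_along(cj)) {
    req <- required_classes(gg$phenotype[i], gg$design)
    if (is.null(req) || is.na(cj[i])) next
    if (!cj[i] %in% req) mism <- c(mism, rownames(gg$calls)[i])
  }
  list(cosegregates = length(mism) == 0L, mismatched = mism)
}
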