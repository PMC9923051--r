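# Readers/writers for the pipeline's table formats. Conventions: 1-based
# inclusive coordinates everywhere internally; TSV/CSV with header row and
# "." for missing; BED conversion (0-based half-open) only at export.

#' Read a pooled variant table
#'
#' @param path input file.
#' @param dialect `"tsv"` (native dialect: columns `chrom`, `pos`, `ref`,
#'   `alt` and `<pool>_ref_depth`/`<pool>_alt_depth`) or `"vcf"` (requires
#'   per-sample `AD` fields; parsed with the vcfR package).
#' @param roles for VCF input, named character vector mapping sample names
#'   to pool/parent prefixes, e.g. `c(S1 = "egusi", S2 = "non_egusi")`;
#'   default: sample names used as-is.
#' @return a `pooled_variant_table` data frame, sorted by chromosome then
#'   position (a warning is raised if the input was unsorted).
#' @export
read_variants <- function(path, dialect = c("tsv", "vcf"), roles = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (dialect == "tsv") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             na.strings = c("NA", "."),
                             colClasses = c(chrom = "character",
                                            ref = "character",
                                            alt = "character"))
    need <- c("chrom", "pos", "ref", "alt")
    miss <- setdiff(need, names(tab))
    if (length(miss))
      stopf("variant TSV %s is missing column(s): %s", path,
            paste(miss, collapse = ", "))
    if (!any(grepl("_alt_depth$", names(tab))))
      stopf("variant TSV %s has no <pool>_alt_depth columns", path)
    if (!is.numeric(tab$pos))
      stopf("non-numeric positions in %s", path)
  } else {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    ad <- vcfR::extract.gt(vcf, element = "AD")
    if (is.null(ad) || all(is.na(ad)))
      stopf("VCF %s has no per-sample AD field", path)
    tab <- data.frame(chrom = vcfR::getCHROM(vcf),
                      pos = as.numeric(vcfR::getPOS(vcf)),
                      ref = vcfR::getREF(vcf), alt = vcfR::getALT(vcf),
                      stringsAsFactors = FALSE)
    for (s in colnames(ad)) {
      prefix <- if (!is.null(roles) && s %in% names(roles)) roles[[s]] else s
      parts <- strsplit(ad[, s], ",", fixed = TRUE)
      tab[[paste0(prefix, "_ref_depth")]] <-
        as.numeric(vapply(parts, `[`, "", 1L))
      tab[[paste0(prefix, "_alt_depth")]] <-
        as.numeric(vapply(parts, function(p) p[2] %||% NA_character_, ""))
    }
  }
  o <- order(tab$chrom, tab$pos)
  if (!identical(o, seq_len(nrow(tab)))) {
    warning(sprintf("input %s was not position-sorted; sorting", path),
            call. = FALSE)
    tab <- tab[o, , drop = FALSE]
    rownames(tab) <- NULL
  }
  pools <- sub("_alt_depth$", "", grep("_alt_depth$", names(tab), value = TRUE))
  structure(tab, class = c("pooled_variant_table", "data.frame"),
            pools = pools)
}

#' Write a pooled variant table as TSV
#'
#' @param tab the table.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_variants <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

#' Export intervals as BED
#'
#' Converts 1-based inclusive intervals to BED's 0-based half-open
#' convention (`start - 1`, `end`), ordered by chromosome then start.
#'
#' @param intervals a [genomic_interval()], a list of them, or a data frame
#'   with `chrom`, `start_bp`, `end_bp` (a `call_regions()` result with
#'   `from_bp`/`to_bp` also works).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_bed <- function(intervals, path) {
  if (inherits(intervals, "genomic_interval")) intervals <- list(intervals)
  if (is.list(intervals) && !is.data.frame(intervals)) {
    intervals <- do.call(rbind, lapply(intervals, function(x)
      data.frame(chrom = x$chrom, start_bp = x$start_bp, end_bp = x$end_bp,
                 stringsAsFactors = FALSE)))
  }
  if (is.null(intervals) || !nrow(intervals)) {
    writeLines(character(), path)
    return(invisible(path))
  }
  if (!is.null(intervals$from_bp)) {
    intervals$start_bp <- intervals$from_bp
    intervals$end_bp <- intervals$to_bp
  }
  intervals <- intervals[order(intervals$chrom, intervals$start_bp), ,
                         drop = FALSE]
  lines <- sprintf("%s\t%s\t%s", intervals$chrom,
                   format(intervals$start_bp - 1, scientific = FALSE,
                          trim = TRUE),
                   format(intervals$end_bp, scientific = FALSE, trim = TRUE))
  writeLines(lines, path)
  invisible(path)
}

#' Write a window scan as TSV
#' @param scan a [window_scan()] result.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_window_table <- function(scan, path) {
  utils::write.table(as.data.frame(scan), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

#' Read a marker panel CSV
#'
#' Columns: `type`, `name`, `chrom`, `pos_bp`, optionally
#' primer columns and `enzyme`.
#'
#' @param path CSV path.
#' @return data frame ordered by chromosome and position.
#' @export
read_marker_panel <- function(path) {
  mk <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", "."))
  need <- c("name", "chrom", "pos_bp")
  miss <- setdiff(need, names(mk))
  if (length(miss))
    stopf("marker panel %s is missing column(s): %s", path,
          paste(miss, collapse = ", "))
  mk[order(mk$chrom, mk$pos_bp), , drop = FALSE]
}

#' Read a genotype matrix CSV
#'
#' Rows are individuals; columns are `id`, one column per marker with calls
#' in `a/h/b` (`-` or empty = missing), and `phenotype`.
#'
#' @param path CSV path.
#' @return list with `calls` (matrix), `phenotype`, `ids`.
#' @export
read_genotype_matrix <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                       na.strings = c("NA", ".", "-", ""))
  if (!all(c("id", "phenotype") %in% names(d)))
    stopf("genotype CSV %s needs 'id' and 'phenotype' columns", path)
  mk_cols <- setdiff(names(d), c("id", "phenotype"))
  calls <- as.matrix(d[mk_cols])
  rownames(calls) <- d$id
  list(calls = calls, phenotype = d$phenotype, ids = d$id)
}

#' Write a population's marker genotypes and phenotypes as CSV
#'
#' @param pop an `egusi_population`.
#' @param markers marker panel data frame (`name`, `chrom`, `pos_bp`).
#' @param path output CSV.
#' @param missing_rate,seed passed to [marker_calls()].
#' @return the path, invisibly.
#' @export
write_population <- function(pop, markers, path, missing_rate = 0,
                             seed = NULL) {
  calls <- marker_calls(pop, markers, missing_rate, seed)
  d <- data.frame(id = rownames(calls), calls, phenotype = pop$phenotype,
                  stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE, na = "-", quote = FALSE)
  invisible(path)
}

#' Write a machine-readable JSON run report
#'
#' @param report named list.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
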