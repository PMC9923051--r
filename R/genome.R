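#' Define a genome for cross simulation
#'
#' A genome is a set of chromosomes with physical (bp) and genetic (cM)
#' lengths and a monotone (here linear) cM-bp correspondence. The default is
#' an 11-chromosome watermelon-like genome of 36.5 Mb per chromosome and
#' 82.2 cM per chromosome, i.e. a total map length of about 904 cM.
#'
#' @param n_chrom number of chromosomes.
#' @param length_bp physical chromosome length(s) in bp; recycled to
#'   `n_chrom`.
#' @param length_cM genetic chromosome length(s) in centimorgans; recycled.
#' @param chrom_names chromosome names; default `Chr01`, `Chr02`, ...
#' @return an object of class `genome_spec` with fields `n_chrom`,
#'   `length_bp`, `length_cM`, `chrom_names`.
#' @examples
#' g <- genome_spec()
#' sum(g$length_cM)  # ~904 cM
#' @export
genome_spec <- function(n_chrom = 11, length_bp = 36.5e6, length_cM = 82.2,
                        chrom_names = sprintf("Chr%02d", seq_len(n_chrom))) {
  if (!is_count(n_chrom)) stopf("`n_chrom` must be a positive integer")
  length_bp <- rep_len(as.numeric(length_bp), n_chrom)
  length_cM <- rep_len(as.numeric(length_cM), n_chrom)
  if (any(!is.finite(length_bp)) || any(length_bp <= 0))
    stopf("chromosome physical lengths must be positive")
  if (any(!is.finite(length_cM)) || any(length_cM < 0))
    stopf("chromosome genetic lengths must be non-negative")
  if (length(chrom_names) != n_chrom || anyDuplicated(chrom_names))
    stopf("`chrom_names` must be %d unique names", n_chrom)
  structure(
    list(n_chrom = as.integer(n_chrom), length_bp = length_bp,
         length_cM = length_cM, chrom_names = as.character(chrom_names)),
    class = "genome_spec")
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf("genome: %d chromosomes, %.1f Mb / %.1f cM total\n",
              x$n_chrom, sum(x$length_bp) / 1e6, sum(x$length_cM)))
  invisible(x)
}

# chromosome argument -> integer index
chrom_index <- function(genome, chrom) {
  if (is.character(chrom)) {
    i <- match(chrom, genome$chrom_names)
    if (any(is.na(i))) stopf("unknown chromosome '%s'", chrom[is.na(i)][1])
    return(i)
  }
  i <- as.integer(chrom)
  if (any(is.na(i)) || any(i < 1) || any(i > genome$n_chrom))
    stopf("chromosome index out of range 1..%d", genome$n_chrom)
  i
}

#' Define a named locus on a genome
#'
#' @param name locus name.
#' @param chrom chromosome index (1-based) or name.
#' @param pos_bp 1-based physical position in bp.
#' @param genome a [genome_spec()]; used to validate the position and derive
#'   the genetic position under the linear cM-bp map.
#' @return an object of class `locus` with fields `name`, `chrom`, `pos_bp`,
#'   `pos_cM`.
#' @export
locus <- function(name, chrom, pos_bp, genome = genome_spec()) {
  i <- chrom_index(genome, chrom)
  pos_bp <- as.numeric(pos_bp)
  if (!is.finite(pos_bp) || pos_bp < 1 || pos_bp > genome$length_bp[i])
    stopf("locus '%s': position %s outside chromosome %s (1..%s bp)",
          name, format(pos_bp), genome$chrom_names[i],
          format(genome$length_bp[i]))
  structure(
    list(name = as.character(name), chrom = i, pos_bp = pos_bp,
         pos_cM = pos_bp / genome$length_bp[i] * genome$length_cM[i]),
    class = "locus")
}

GENO_MAIN <- c("AA", "Aa", "aa")
GENO_SUPP <- c("BB", "Bb", "bb")

#' Two-locus epistasis model (penetrance table)
#'
#' Maps every combination of main-locus genotype (`AA`, `Aa`, `aa`) and
#' suppressor-locus genotype (`BB`, `Bb`, `bb`) to a seed phenotype. The
#' default penetrance encodes inhibitory epistasis by a recessive suppressor:
#' seeds are egusi exactly when the plant is homozygous recessive at the main
#' locus (`aa`) and carries at least one dominant, non-suppressing allele at
#' the suppressor locus (`BB` or `Bb`). In an F2 this yields the 13:3
#' non-egusi : egusi ratio.
#'
#' @param main_locus,suppressor_locus [locus()] objects; must sit on
#'   different chromosomes for exact ratio enumeration.
#' @param penetrance 3x3 character matrix with rownames `AA,Aa,aa`,
#'   colnames `BB,Bb,bb` and values in `c("egusi", "non_egusi")`.
#' @return an object of class `epistasis_model`.
#' @seealso [assign_phenotype()], [enumerate_ratio()]
#' @export
epistasis_model <- function(main_locus, suppressor_locus,
                            penetrance = default_penetrance()) {
  if (!inherits(main_locus, "locus") || !inherits(suppressor_locus, "locus"))
    stopf("loci must be created with locus()")
  if (!is.matrix(penetrance) || !identical(dim(penetrance), c(3L, 3L)) ||
      !identical(rownames(penetrance), GENO_MAIN) ||
      !identical(colnames(penetrance), GENO_SUPP))
    stopf("`penetrance` must be a 3x3 matrix with rownames AA,Aa,aa and colnames BB,Bb,bb")
  if (!all(penetrance %in% c("egusi", "non_egusi")))
    stopf("penetrance values must be 'egusi' or 'non_egusi'")
  structure(list(main_locus = main_locus, suppressor_locus = suppressor_locus,
                 penetrance = penetrance),
            class = "epistasis_model")
}

#' @rdname epistasis_model
#' @export
default_penetrance <- function() {
  p <- matrix("non_egusi", 3, 3, dimnames = list(GENO_MAIN, GENO_SUPP))
  p["aa", c("BB", "Bb")] <- "egusi"
  p
}

#' Default egusi model on a genome
#'
#' Main (eg) locus on chromosome 6 near 7.0 Mb; recessive suppressor on
#' chromosome 1 near 33.0 Mb (the two BSA-seq QTL regions).
#'
#' @param genome a [genome_spec()].
#' @return an `epistasis_model`.
#' @export
default_epistasis_model <- function(genome = genome_spec()) {
  epistasis_model(
    main_locus = locus("eg", 6, 7.0e6, genome),
    suppressor_locus = locus("su", 1, 33.0e6, genome))
}

#' Specify an inbred parent line
#'
#' Parents are fully homozygous at both model loci. `tracked` flags the line
#' whose alleles are counted in pooled read simulation (by convention the
#' egusi donor B3, whose allele is the "alt" allele of variant tables).
#'
#' @param name line name.
#' @param main genotype at the main locus: `"AA"` or `"aa"`.
#' @param suppressor genotype at the suppressor locus: `"BB"` or `"bb"`.
#' @param tracked logical; is this the read-simulation reference line?
#' @return an object of class `parent_spec`.
#' @export
parent_spec <- function(name, main, suppressor, tracked = FALSE) {
  if (!main %in% c("AA", "aa"))
    stopf("parent '%s' must be homozygous at the main locus (AA or aa)", name)
  if (!suppressor %in% c("BB", "bb"))
    stopf("parent '%s' must be homozygous at the suppressor locus (BB or bb)",
          name)
  structure(list(name = as.character(name), main = main,
                 suppressor = suppressor, tracked = isTRUE(tracked)),
            class = "parent_spec")
}

#' Default parent lines
#'
#' B3: the egusi donor, `aa BB` (recessive at eg, dominant non-suppressing at
#' the suppressor locus). X1625: thick black seed coat, `AA bb`. B4: thick
#' yellow seed coat, `AA BB` -- the one assignment that reproduces every
#' observed segregation ratio of the B3 x B4 crosses and chromosome-6
#' mapping.
#'
#' @return named list of [parent_spec()] objects `B3`, `X1625`, `B4`.
#' @export
default_parents <- function() {
  list(B3    = parent_spec("B3", "aa", "BB", tracked = TRUE),
       X1625 = parent_spec("X1625", "AA", "bb"),
       B4    = parent_spec("B4", "AA", "BB"))
}

#' Phenotype of a two-locus genotype under an epistasis model
#'
#' Deterministic lookup in the model's penetrance table; vectorized over
#' genotype pairs.
#'
#' @param main character vector of main-locus genotypes in `AA,Aa,aa`.
#' @param suppressor character vector of suppressor genotypes in `BB,Bb,bb`.
#' @param model an [epistasis_model()].
#' @return character vector of phenotypes (`"egusi"` / `"non_egusi"`).
#' @examples
#' m <- default_epistasis_model()
#' assign_phenotype("aa", "BB", m)  # egusi
#' assign_phenotype("Aa", "Bb", m)  # non_egusi
#' @export
assign_phenotype <- function(main, suppressor, model) {
  i <- match(main, GENO_MAIN)
  j <- match(suppressor, GENO_SUPP)
  if (any(is.na(i))) stopf("unknown main-locus genotype '%s'",
                           main[is.na(i)][1])
  if (any(is.na(j))) stopf("unknown suppressor genotype '%s'",
                           suppressor[is.na(j)][1])
  model$penetrance[cbind(i, j)]
}
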