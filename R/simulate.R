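# Forward simulation of biparental crosses.
#
# Each individual carries, per chromosome, two homolog "origin tracks": a
# run-length encoding (segment right ends in bp + founder index 1/2) of which
# founder line each stretch of the homolog descends from. Founders are
# inbred, so founder origin determines the allele everywhere.

founder_individual <- function(founder, genome) {
  chroms <- lapply(genome$length_bp, function(L) {
    h <- list(ends = L, orig = as.integer(founder))
    list(h, h)
  })
  structure(list(chroms = chroms), class = "egusi_individual")
}

# origin of homolog `h` at physical position(s) pos
orig_at <- function(h, pos) {
  h$orig[findInterval(pos, h$ends, left.open = TRUE) + 1L]
}

# sub-track of homolog `h` over the interval (a, b], 0 <= a < b <= L
track_slice <- function(h, a, b) {
  i1 <- findInterval(a, h$ends) + 1L
  i2 <- findInterval(b, h$ends, left.open = TRUE) + 1L
  ends <- h$ends[i1:i2]
  ends[length(ends)] <- b
  list(ends = ends, orig = h$orig[i1:i2])
}

merge_track <- function(ends, orig) {
  if (length(orig) > 1L) {
    keep <- c(orig[-1L] != orig[-length(orig)], TRUE)
    ends <- ends[keep]
    orig <- orig[keep]
  }
  list(ends = ends, orig = orig)
}

#' Simulate one gamete from an individual
#'
#' Meiosis under the Haldane model (no crossover interference): per
#' chromosome the crossover count is Poisson with mean equal to the genetic
#' length in Morgans, crossover positions are uniform along the chromosome
#' (the linear cM-bp map makes uniform-in-cM and uniform-in-bp coincide),
#' and the gamete alternates between the two homologs at each crossover,
#' starting from a fair random homolog.
#'
#' @param parent an individual (element of a population's `individuals`), or
#'   a founder index 1/2 wrapped by the internal founder constructor.
#' @param genome a [genome_spec()].
#' @param seed optional integer seed (RNG state is restored on exit).
#' @return a haploid origin track: list of per-chromosome
#'   `list(ends, orig)` run-length encodings.
#' @export
simulate_gamete <- function(parent, genome, seed = NULL) {
  if (!inherits(genome, "genome_spec")) stopf("invalid genome specification")
  with_seed(seed, {
    lapply(seq_len(genome$n_chrom), function(i) {
      gamete_chrom(parent$chroms[[i]], genome$length_bp[i],
                   genome$length_cM[i])
    })
  })
}

gamete_chrom <- function(homologs, L_bp, L_cM) {
  k <- stats::rpois(1L, L_cM / 100)
  s <- sample.int(2L, 1L)
  if (k == 0L) return(homologs[[s]])
  xo <- sort(stats::runif(k, 0, L_bp))
  bounds <- c(0, xo, L_bp)
  use <- rep_len(c(s, 3L - s), k + 1L)
  ends <- vector("list", k + 1L)
  orig <- vector("list", k + 1L)
  for (j in seq_len(k + 1L)) {
    sl <- track_slice(homologs[[use[j]]], bounds[j], bounds[j + 1L])
    ends[[j]] <- sl$ends
    orig[[j]] <- sl$orig
  }
  merge_track(unlist(ends), unlist(orig))
}

offspring <- function(mother, father, genome) {
  gm <- simulate_gamete(mother, genome)
  gf <- simulate_gamete(father, genome)
  chroms <- lapply(seq_len(genome$n_chrom), function(i) list(gm[[i]], gf[[i]]))
  structure(list(chroms = chroms), class = "egusi_individual")
}

# dosage (0/1/2) of founder `founder` in `ind` at sorted positions on chrom i
dosage_at <- function(ind, chrom, pos, founder = 1L) {
  hs <- ind$chroms[[chrom]]
  (orig_at(hs[[1L]], pos) == founder) + (orig_at(hs[[2L]], pos) == founder)
}

# two-locus genotype classes of one individual under a model + parent pair
locus_genotypes <- function(ind, model, parents) {
  main_alleles <- substr(c(parents[[1]]$main, parents[[2]]$main), 1, 1)
  supp_alleles <- substr(c(parents[[1]]$suppressor, parents[[2]]$suppressor),
                         1, 1)
  ml <- model$main_locus; sl <- model$suppressor_locus
  om <- c(orig_at(ind$chroms[[ml$chrom]][[1]], ml$pos_bp),
          orig_at(ind$chroms[[ml$chrom]][[2]], ml$pos_bp))
  os <- c(orig_at(ind$chroms[[sl$chrom]][[1]], sl$pos_bp),
          orig_at(ind$chroms[[sl$chrom]][[2]], sl$pos_bp))
  n_a <- sum(main_alleles[om] == "a")
  n_b <- sum(supp_alleles[os] == "b")
  c(main = GENO_MAIN[n_a + 1L], suppressor = GENO_SUPP[n_b + 1L])
}

#' Simulate a cross population
#'
#' Generates `n` individuals of the requested pedigree from a pair of inbred
#' parents, then assigns each a seed phenotype by looking its two-locus
#' genotype up in the epistasis model's penetrance table.
#'
#' Pedigrees: `"F1"` (P1 x P2), `"F2"` (selfed F1), `"BC1F1"` (F1 backcrossed
#' to P1, the recurrent parent), and `"BC1F2"` (a given BC1F1 individual
#' selfed; supply it as `bc1_individual`, e.g. picked from a simulated BC1F1
#' population).
#'
#' @param pedigree one of `"F1"`, `"F2"`, `"BC1F1"`, `"BC1F2"`.
#' @param parents list of two [parent_spec()]s, recurrent/donor first (P1).
#' @param n number of offspring.
#' @param model an [epistasis_model()].
#' @param genome a [genome_spec()].
#' @param seed integer seed; fixed seed gives a bit-identical population.
#' @param bc1_individual for `pedigree = "BC1F2"`, the BC1F1 plant to self.
#' @return an object of class `egusi_population`: list with `individuals`,
#'   `main_geno`, `supp_geno`, `phenotype`, plus the simulation metadata.
#' @examples
#' p <- default_parents()
#' pop <- make_cross("F2", list(p$B3, p$X1625), n = 200,
#'                   model = default_epistasis_model(), seed = 1)
#' table(pop$phenotype)  # close to 13:3 non-egusi : egusi
#' @export
make_cross <- function(pedigree, parents, n, model = default_epistasis_model(),
                       genome = genome_spec(), seed = NULL,
                       bc1_individual = NULL) {
  if (!is_count(n)) stopf("`n` must be a positive integer")
  if (length(parents) != 2L ||
      !all(vapply(parents, inherits, TRUE, "parent_spec")))
    stopf("`parents` must be a list of two parent_spec objects")
  pedigree <- match.arg(pedigree, c("F1", "F2", "BC1F1", "BC1F2"))
  inds <- with_seed(seed, {
    p1 <- founder_individual(1L, genome)
    p2 <- founder_individual(2L, genome)
    switch(pedigree,
      F1 = replicate(n, offspring(p1, p2, genome), simplify = FALSE),
      F2 = {
        f1a <- offspring(p1, p2, genome)
        f1b <- offspring(p1, p2, genome)
        replicate(n, offspring(f1a, f1b, genome), simplify = FALSE)
      },
      BC1F1 = {
        f1 <- offspring(p1, p2, genome)
        replicate(n, offspring(f1, p1, genome), simplify = FALSE)
      },
      BC1F2 = {
        if (is.null(bc1_individual))
          stopf("pedigree 'BC1F2' requires `bc1_individual` (the BC1 plant to self)")
        replicate(n, offspring(bc1_individual, bc1_individual, genome),
                  simplify = FALSE)
      })
  })
  gt <- vapply(inds, locus_genotypes, character(2), model = model,
               parents = parents)
  pop <- list(individuals = inds,
              main_geno = unname(gt["main", ]),
              supp_geno = unname(gt["suppressor", ]),
              phenotype = unname(assign_phenotype(gt["main", ],
                                                  gt["suppressor", ], model)),
              pedigree = pedigree, parents = parents, model = model,
              genome = genome, n = as.integer(n), seed = seed)
  class(pop) <- "egusi_population"
  pop
}

#' @export
print.egusi_population <- function(x, ...) {
  tab <- table(factor(x$phenotype, c("non_egusi", "egusi")))
  cat(sprintf("%s population of %d (%s x %s): %d non-egusi : %d egusi\n",
              x$pedigree, x$n, x$parents[[1]]$name, x$parents[[2]]$name,
              tab[1], tab[2]))
  invisible(x)
}

# founder index of the tracked (read-simulation reference) parent; default 1
tracked_founder <- function(parents) {
  tr <- which(vapply(parents, function(p) p$tracked, TRUE))
  if (length(tr) == 1L) tr else 1L
}

#' Genotype calls of a population at a marker panel
#'
#' Codes each individual at each marker by tracked-founder allele dosage:
#' `a` = homozygous tracked/recurrent parent (dosage 2), `h` = heterozygous,
#' `b` = homozygous other parent. A per-marker missing rate can be applied
#' (calls set to `NA`) to emulate incomplete genotyping.
#'
#' @param pop an `egusi_population`.
#' @param markers data frame with columns `name`, `chrom`, `pos_bp`.
#' @param missing_rate probability a call is missing.
#' @param seed seed for the missingness draw.
#' @return character matrix (individuals x markers) with values `a/h/b/NA`.
#' @export
marker_calls <- function(pop, markers, missing_rate = 0, seed = NULL) {
  founder <- tracked_founder(pop$parents)
  calls <- matrix(NA_character_, pop$n, nrow(markers),
                  dimnames = list(sprintf("ind%03d", seq_len(pop$n)),
                                  markers$name))
  for (j in seq_len(nrow(markers))) {
    ci <- chrom_index(pop$genome, markers$chrom[j])
    d <- vapply(pop$individuals, dosage_at, numeric(1), chrom = ci,
                pos = markers$pos_bp[j], founder = founder)
    calls[, j] <- c("b", "h", "a")[d + 1L]
  }
  if (missing_rate > 0) {
    calls <- with_seed(seed, {
      drop <- matrix(stats::runif(length(calls)) < missing_rate,
                     nrow(calls))
      calls[drop] <- NA_character_
      calls
    })
  }
  calls
}

#' Draw phenotype-defined pools from a population
#'
#' @param pop an `egusi_population`.
#' @param size pool size (default 20 plants per pool).
#' @param seed seed for the sampling.
#' @return named list with integer index vectors `egusi` and `non_egusi`.
#' @export
make_pools <- function(pop, size = 20, seed = NULL) {
  eg <- which(pop$phenotype == "egusi")
  ne <- which(pop$phenotype == "non_egusi")
  if (length(eg) < size || length(ne) < size)
    stopf("population has only %d egusi / %d non-egusi plants; need %d each",
          length(eg), length(ne), size)
  with_seed(seed, list(egusi = sample(eg, size), non_egusi = sample(ne, size)))
}

#' Simulate pooled sequencing allele counts
#'
#' For each SNP position and pool, the true tracked-parent allele frequency
#' is the mean allelic dosage over the pooled plants divided by two; read
#' depth is Poisson(`mean_depth`) and tracked-allele ("alt") read counts are
#' Binomial(depth, f(1-e) + (1-f)e) with sequencing error rate `e`.
#'
#' @param pop an `egusi_population`.
#' @param pools named list of integer index vectors (e.g. from
#'   [make_pools()]); names become the pool column prefixes.
#' @param snp_positions named list (chromosome name -> sorted bp positions),
#'   or a data frame with columns `chrom`, `pos`.
#' @param mean_depth mean sequencing depth per SNP per pool.
#' @param error_rate per-read error rate in `[0, 0.5)`.
#' @param seed integer seed.
#' @return a `pooled_variant_table` data frame with columns `chrom`, `pos`,
#'   `ref`, `alt` and `<pool>_ref_depth`, `<pool>_alt_depth` per pool. The
#'   alt allele is the tracked (B3-origin) allele.
#' @export
simulate_pooled_counts <- function(pop, pools, snp_positions, mean_depth = 30,
                                   error_rate = 0, seed = NULL) {
  if (mean_depth <= 0) stopf("`mean_depth` must be positive")
  if (error_rate < 0 || error_rate >= 0.5)
    stopf("`error_rate` must be in [0, 0.5)")
  if (any(!lengths(pools))) stopf("pools must be non-empty")
  if (is.data.frame(snp_positions))
    snp_positions <- split(snp_positions$pos, snp_positions$chrom)
  founder <- tracked_founder(pop$parents)
  genome <- pop$genome
  rows <- list()
  for (cn in names(snp_positions)) {
    ci <- chrom_index(genome, cn)
    pos <- sort(as.numeric(snp_positions[[cn]]))
    if (!length(pos)) next
    if (any(pos < 1) || any(pos > genome$length_bp[ci]))
      stopf("SNP position outside chromosome %s", cn)
    row <- data.frame(chrom = genome$chrom_names[ci], pos = pos,
                      ref = "A", alt = "T", stringsAsFactors = FALSE)
    for (pn in names(pools)) {
      dose <- rowSums(vapply(pools[[pn]], function(i)
        dosage_at(pop$individuals[[i]], ci, pos, founder), numeric(length(pos))))
      row[[paste0(pn, "_true_f")]] <- dose / (2 * length(pools[[pn]]))
    }
    rows[[cn]] <- row
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab <- with_seed(seed, {
    for (pn in names(pools)) {
      f <- tab[[paste0(pn, "_true_f")]]
      depth <- stats::rpois(nrow(tab), mean_depth)
      p_alt <- f * (1 - error_rate) + (1 - f) * error_rate
      alt <- stats::rbinom(nrow(tab), depth, p_alt)
      tab[[paste0(pn, "_ref_depth")]] <- depth - alt
      tab[[paste0(pn, "_alt_depth")]] <- alt
      tab[[paste0(pn, "_true_f")]] <- NULL
    }
    tab
  })
  structure(tab, class = c("pooled_variant_table", "data.frame"),
            pools = names(pools))
}
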