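# Genetics of the evolving asymptotic-length trait: a diploid quantitative
# trait with binary alleles, Mendelian transmission, environmental noise at
# expression, and a negative log-log coupling between Linf and the von
# Bertalanffy growth rate k.
#
# Genotype layout: an integer vector of 2 * n_loci alleles in {0, 1};
# locus j occupies positions 2j-1 (maternally derived copy) and 2j
# (paternally derived copy). The genotypic score is the allele sum, so at
# the default 10 loci it ranges over 0..20.

#' Draw a founder genotype
#'
#' Each allele is an independent Bernoulli(`allele_freq`) draw, giving a
#' binomial genotypic score with mean `2 * n_loci * allele_freq`.
#'
#' @param n_loci Number of diploid loci.
#' @param allele_freq Founder frequency of the 1 allele, in `[0, 1]`.
#' @return Integer vector of `2 * n_loci` alleles in `{0, 1}`.
#' @examples
#' set.seed(1)
#' g <- founder_genotype()
#' genotype_value(g)
#' @export
founder_genotype <- function(n_loci = 10L, allele_freq = 0.5) {
  .check_number(n_loci, "n_loci", lower = 1)
  .check_number(allele_freq, "allele_freq", lower = 0, upper = 1)
  as.integer(stats::runif(2L * as.integer(n_loci)) < allele_freq)
}

#' Genotypic score of a genotype
#'
#' @param genotype Integer allele vector as returned by
#'   [founder_genotype()] or [inherit()].
#' @return The allele sum.
#' @export
genotype_value <- function(genotype) {
  .check_genotype(genotype)
  sum(genotype)
}

.check_genotype <- function(g) {
  if (!is.numeric(g) || length(g) < 2L || length(g) %% 2L != 0L ||
      anyNA(g) || any(g != 0L & g != 1L)) {
    stop("a genotype must be an even-length vector of 0/1 alleles",
         call. = FALSE)
  }
  invisible(g)
}

#' Mendelian inheritance
#'
#' At every locus the offspring receives one allele drawn uniformly from
#' the dam's two copies and one drawn uniformly from the sire's two
#' copies. There is no mutation; alleles stay in `{0, 1}` and the expected
#' offspring score equals the midparent score.
#'
#' @param dam,sire Parental genotypes with the same locus count.
#' @return An offspring genotype (integer vector, same layout).
#' @examples
#' set.seed(1)
#' off <- inherit(rep(1L, 20), rep(0L, 20))
#' genotype_value(off) # forced heterozygosity: exactly 10
#' @export
inherit <- function(dam, sire) {
  .check_genotype(dam)
  .check_genotype(sire)
  if (length(dam) != length(sire)) {
    stop("`dam` and `sire` must have the same number of loci", call. = FALSE)
  }
  G <- rbind(as.integer(dam), as.integer(sire))
  drop(.mendelian_offspring(G, 1L, 2L))
}

# Vectorised Mendelian transmission. G is an n x (2L) allele matrix; dam
# and sire are row indices (recycled per offspring). Returns an allele
# matrix with one row per offspring, dam-derived gametes in odd columns.
.mendelian_offspring <- function(G, dam, sire) {
  n <- max(length(dam), length(sire))
  L <- ncol(G) %/% 2L
  odd <- 2L * seq_len(L) - 1L
  even <- odd + 1L
  pick_gamete <- function(parent_rows) {
    a <- G[parent_rows, odd, drop = FALSE]
    b <- G[parent_rows, even, drop = FALSE]
    swap <- matrix(stats::runif(n * L) < 0.5, n, L)
    a[swap] <- b[swap]
    a
  }
  out <- matrix(0L, n, 2L * L)
  out[, odd] <- pick_gamete(dam)
  out[, even] <- pick_gamete(sire)
  storage.mode(out) <- "integer"
  out
}

#' Express the asymptotic-length phenotype
#'
#' Adds normal environmental noise (`noise_sd`, score units) to the
#' genotypic score once, at birth, then maps the noisy score to cm through
#' the affine expression map, truncating below at `linf_floor_cm`. The
#' phenotype is fixed for life.
#'
#' @param genotype Integer allele vector.
#' @param params An [expression_params()] object.
#' @return Phenotypic asymptotic length (cm).
#' @export
express_linf <- function(genotype, params = expression_params()) {
  g <- genotype_value(genotype)
  .express_scores(g, params)
}

# Vectorised expression of genotypic scores into Linf phenotypes.
.express_scores <- function(g, params) {
  s <- g + stats::rnorm(length(g), mean = 0, sd = params$noise_sd)
  pmax(params$linf_floor_cm,
       params$intercept_cm + params$slope_cm_per_score * s)
}

#' Growth rate from asymptotic length
#'
#' The von Bertalanffy growth rate is coupled to the asymptotic length by
#' `k = exp(growth_alpha + growth_beta * log(linf))`, strictly decreasing
#' in `linf` for negative `growth_beta`. The default calibration gives
#' `k = 0.0825 / yr` at 80 cm.
#'
#' @param linf Asymptotic length (cm), vectorised, strictly positive.
#' @param params An [expression_params()] object.
#' @return Growth rate k (per year).
#' @examples
#' k_from_linf(80) # 0.0825
#' @export
k_from_linf <- function(linf, params = expression_params()) {
  if (!is.numeric(linf) || any(!is.finite(linf)) || any(linf <= 0)) {
    stop("`linf` must be positive and finite", call. = FALSE)
  }
  exp(params$growth_alpha + params$growth_beta * log(linf))
}

#' Estimate narrow-sense heritability by midparent-offspring regression
#'
#' Simulates `n_trios` dam-sire-offspring trios from founder genotypes,
#' expresses all phenotypes with the same expression map, and returns the
#' slope of the offspring-on-midparent phenotype regression, the standard
#' quantitative-genetics estimator of narrow-sense heritability.
#'
#' @param n_trios Number of independent trios.
#' @param n_loci,allele_freq Founder genetic architecture.
#' @param params An [expression_params()] object.
#' @return The regression slope (an h-squared estimate).
#' @examples
#' set.seed(1)
#' estimate_heritability(2000)
#' @export
estimate_heritability <- function(n_trios = 10000,
                                  n_loci = 10L, allele_freq = 0.5,
                                  params = expression_params()) {
  .check_number(n_trios, "n_trios", lower = 2)
  n <- as.integer(n_trios)
  G_dam <- .founder_allele_matrix(n, n_loci, allele_freq)
  G_sire <- .founder_allele_matrix(n, n_loci, allele_freq)
  G_off <- .mendelian_offspring(rbind(G_dam, G_sire),
                                seq_len(n), n + seq_len(n))
  ph_dam <- .express_scores(rowSums(G_dam), params)
  ph_sire <- .express_scores(rowSums(G_sire), params)
  ph_off <- .express_scores(rowSums(G_off), params)
  mid <- (ph_dam + ph_sire) / 2
  unname(stats::coef(stats::lm(ph_off ~ mid))[2L])
}

# n x (2 * n_loci) matrix of independent founder alleles.
.founder_allele_matrix <- function(n, n_loci, allele_freq) {
  m <- 2L * as.integer(n_loci)
  matrix(as.integer(stats::runif(n * m) < allele_freq), n, m)
}
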