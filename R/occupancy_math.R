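#' Constants of the occupancy combinatorics calculus
#'
#' @param n_tf number of TFs available (human-scale default 1600).
#' @param cooperativity fraction of TF pairs with cooperative (spacing and
#'   orientation constrained) dimeric binding; default 0.03.
#' @param genome_size haploid genome size in bp; default 3e9.
#' @param effective_lengths map arity -> effective motif length in bp
#'   (IC / 2); defaults 6, 8, 12.25, 16.25, 21, 25.5 for 1..6 TFs.
#' @param window regulatory-element window size in bp; default 200.
#' @param site_length effective length of a single TF site; default 6.
#' @param hit_probability per-TF probability of a perfect site in one window.
#'   Default exactly 1/20: the rounded constant used throughout the Poisson
#'   specificity framework (the derivation window/4^site_length ~ 0.0488 is
#'   available as [site_hit_probability()]).
#' @param n_master number of master regulators; default 0.
#' @param active_band feasible band of genome-wide active-site counts;
#'   default c(30000, 200000).
#' @param strand_factor strands counted in the individual-hit expectation;
#'   default 1 (single-strand convention, which reproduces the published
#'   7.3e5 for a 6-bp site), 2 for the double-strand convention.
#' @return object of class `OccupancyParams`.
#' @export
occupancy_params <- function(n_tf = 1600,
                             cooperativity = 0.03,
                             genome_size = 3e9,
                             effective_lengths = c(`1` = 6, `2` = 8,
                                                   `3` = 12.25, `4` = 16.25,
                                                   `5` = 21, `6` = 25.5),
                             window = 200,
                             site_length = 6,
                             hit_probability = 1 / 20,
                             n_master = 0,
                             active_band = c(30000, 200000),
                             strand_factor = 1) {
  stopifnot(cooperativity > 0, cooperativity <= 1, genome_size >= 0,
            all(diff(effective_lengths) > 0), window >= 0, site_length >= 1,
            hit_probability > 0, hit_probability <= 1, n_master >= 0,
            length(active_band) == 2, active_band[1] <= active_band[2],
            strand_factor %in% c(1, 2))
  structure(list(n_tf = n_tf, cooperativity = cooperativity,
                 genome_size = genome_size,
                 effective_lengths = effective_lengths, window = window,
                 site_length = site_length,
                 hit_probability = hit_probability, n_master = n_master,
                 active_band = active_band, strand_factor = strand_factor),
            class = "OccupancyParams")
}

eff_len <- function(p, k) {
  el <- p$effective_lengths[as.character(k)]
  if (anyNA(el)) stop("no effective length configured for arity ", k)
  unname(el)
}

#' Number of possible k-TF multimeric motifs
#'
#' Ordered k-sequences over n TFs, collapsed by the factor of 2 for
#' reverse-complement symmetry when k >= 2: n for k = 1, else n^k / 2.
#'
#' @param n number of TFs.
#' @param k motif arity.
#' @return real count.
#' @export
possible_combinations <- function(n, k) {
  stopifnot(n >= 0, k >= 1)
  if (k == 1) n else n^k / 2
}

#' Fraction of k-TF combinations whose members all cooperate
#'
#' c^(k-1): each successive junction cooperates independently with
#' probability c.
#'
#' @param c pairwise cooperativity rate.
#' @param k motif arity.
#' @return fraction in [0, 1].
#' @export
cooperating_fraction <- function(c, k) {
  stopifnot(k >= 1)
  c^(k - 1)
}

#' Expected number of distinct k-TF multimeric motifs
#'
#' possible combinations times the cooperating fraction.
#'
#' @param p OccupancyParams.
#' @param k motif arity.
#' @return real count.
#' @export
expected_motif_count <- function(p, k) {
  possible_combinations(p$n_tf, k) * cooperating_fraction(p$cooperativity, k)
}

#' Expected genome hits of one k-TF motif
#'
#' strand_factor * G * 4^(-L_eff(k)): the chance a random position matches a
#' site of the motif's effective length.
#'
#' @param p OccupancyParams.
#' @param k motif arity.
#' @return expected hit count (real).
#' @export
individual_hit_expectation <- function(p, k) {
  p$strand_factor * p$genome_size * 4^(-eff_len(p, k))
}

#' Expected total genome hits over all k-TF motifs
#'
#' @param p OccupancyParams.
#' @param k motif arity.
#' @return expected count (real).
#' @export
total_hit_expectation <- function(p, k) {
  expected_motif_count(p, k) * individual_hit_expectation(p, k)
}

#' Smallest arity at which motif diversity exceeds the regulatory repertoire
#'
#' The smallest k (up to 6) whose expected motif count exceeds the number of
#' distinct regulatory sites in the genome; uniqueness of regulatory sequence
#' under a strict-geometry model requires at least this arity.
#'
#' @param p OccupancyParams.
#' @param n_regulatory number of distinct regulatory sites (default 3e6).
#' @return integer arity, or NA if no k <= 6 qualifies.
#' @export
uniqueness_arity <- function(p, n_regulatory = 3e6) {
  stopifnot(n_regulatory > 0)
  for (k in 1:6) {
    if (expected_motif_count(p, k) > n_regulatory) return(k)
  }
  NA_integer_
}

#' Per-window single-site hit probability, derived
#'
#' window / 4^site_length, capped at 1: for a 200-bp window and a 6-bp
#' effective site, 200/4096 ~ 1/20. The Poisson framework uses the rounded
#' 1/20 (see [occupancy_params()]).
#'
#' @param p OccupancyParams.
#' @return probability.
#' @export
site_hit_probability <- function(p) {
  min(1, p$window / 4^p$site_length)
}

#' Expected spacing between perfect site matches
#'
#' 4^site_length / strands bp: a perfect match to a non-palindromic 6-mer
#' occurs about every 2 kb when both strands are searched.
#'
#' @param site_length site length in bp.
#' @param strands 1 or 2.
#' @return expected spacing in bp.
#' @export
site_match_spacing <- function(site_length = 6, strands = 2) {
  4^site_length / strands
}

#' Poisson tail probability of at least x TFBS hits in a window
#'
#' P(Poisson(lambda) >= x) with lambda = n_active * hit_probability
#' (default 1/20 per active TF).
#'
#' @param n_active number of TFs active in the cell type.
#' @param x hit count.
#' @param p OccupancyParams.
#' @return probability.
#' @export
poisson_tail <- function(n_active, x, p = occupancy_params()) {
  stopifnot(n_active >= 0, x >= 0)
  lambda <- n_active * p$hit_probability
  ppois(x - 1, lambda, lower.tail = FALSE)
}

#' Minimum TFBS count for genome-level specificity
#'
#' Smallest X with P(Poisson >= X) at or below the fraction of the genome
#' allowed to score positive (~0.5-3% of windows are active regulatory
#' elements; default band 3%).
#'
#' @param n_active number of active TFs.
#' @param p OccupancyParams.
#' @param max_positive_fraction allowed positive fraction in (0, 1).
#' @return integer site count.
#' @export
min_sites_for_specificity <- function(n_active, p = occupancy_params(),
                                      max_positive_fraction = 0.03) {
  stopifnot(max_positive_fraction > 0, max_positive_fraction < 1)
  x <- 0
  while (poisson_tail(n_active, x, p) > max_positive_fraction) x <- x + 1
  x
}

#' Specificity probability adjusted for a master-regulator requirement
#'
#' The plain Poisson tail multiplied by the probability of exactly one master
#' regulator hit, Poisson PMF(1; m * hit_probability).
#'
#' @param n_active number of active (non-master) TFs.
#' @param x required TFBS hits.
#' @param m number of master regulators available to the cell.
#' @param p OccupancyParams.
#' @return probability.
#' @export
mr_adjusted_probability <- function(n_active, x, m, p = occupancy_params()) {
  stopifnot(m >= 0)
  poisson_tail(n_active, x, p) * dpois(1, m * p$hit_probability)
}

#' k-TF combinations containing at least one master regulator
#'
#' Ordered k-sequences over n TFs that include at least one of m designated
#' master regulators, collapsed by the reverse-complement factor of 2:
#' (n^k - (n-m)^k) / 2.
#'
#' @param n number of TFs.
#' @param k motif arity.
#' @param m number of master regulators (0 <= m <= n).
#' @return real count.
#' @export
mr_constrained_combinations <- function(n, k, m) {
  if (m > n) stop("m must not exceed n")
  stopifnot(m >= 0, k >= 1)
  (n^k - (n - m)^k) / 2
}

#' Expected total genome hits under a master-regulator constraint
#'
#' As [total_hit_expectation()] but counting only combinations containing at
#' least one of m master regulators; m = 0 means no constraint.
#'
#' @param p OccupancyParams.
#' @param k motif arity.
#' @param m number of master regulators.
#' @return expected count.
#' @export
mr_total_hit_expectation <- function(p, k, m = p$n_master) {
  combos <- if (m == 0) possible_combinations(p$n_tf, k) else
    mr_constrained_combinations(p$n_tf, k, m)
  combos * cooperating_fraction(p$cooperativity, k) *
    individual_hit_expectation(p, k)
}

#' Number of expressed TFs putting expected k-TF hits in the feasible band
#'
#' Scans n = step, 2*step, ... up to n_tf and returns the smallest n whose
#' total hit expectation lies within `active_band` (default 30,000-200,000
#' active regulatory sites).
#'
#' @param k motif arity.
#' @param p OccupancyParams.
#' @param step scan increment (default 100).
#' @param m number of obligatory master regulators (0 = none).
#' @return smallest qualifying n, or NA if none up to n_tf.
#' @export
tf_count_for_target_sites <- function(k, p = occupancy_params(), step = 100,
                                      m = 0) {
  stopifnot(step >= 1)
  for (n in seq(step, p$n_tf, by = step)) {
    pn <- p
    pn$n_tf <- n
    tot <- mr_total_hit_expectation(pn, k, m)
    if (tot >= p$active_band[1] && tot <= p$active_band[2]) return(n)
  }
  NA_integer_
}

#' The multimeric-motif occupancy table
#'
#' One column per arity 1..6: possible combinations, percent that cooperate,
#' expected number of motifs, effective motif length, expected hits of an
#' individual motif in the genome, and expected total hits.
#'
#' @param p OccupancyParams.
#' @return data.frame with a `quantity` column and columns `k1`..`k6`.
#' @export
table2 <- function(p = occupancy_params()) {
  ks <- as.integer(names(p$effective_lengths))
  rows <- list(
    possible_combinations = vapply(ks, function(k)
      possible_combinations(p$n_tf, k), numeric(1)),
    percent_cooperate = vapply(ks, function(k)
      100 * cooperating_fraction(p$cooperativity, k), numeric(1)),
    expected_motifs = vapply(ks, function(k)
      expected_motif_count(p, k), numeric(1)),
    effective_length = vapply(ks, function(k) eff_len(p, k), numeric(1)),
    individual_hits = vapply(ks, function(k)
      individual_hit_expectation(p, k), numeric(1)),
    total_hits = vapply(ks, function(k)
      total_hit_expectation(p, k), numeric(1))
  )
  out <- data.frame(quantity = names(rows),
                    do.call(rbind, rows), row.names = NULL)
  names(out)[-1] <- paste0("k", ks)
  out
}

#' Poisson specificity grid (heatmap data)
#'
#' Long-format grid of P(>= x hits), optionally master-regulator adjusted,
#' over numbers of active TFs and required hit counts.
#'
#' @param n_active_values numbers of active TFs.
#' @param x_values required hit counts.
#' @param m_values master-regulator counts (0 = unadjusted).
#' @param p OccupancyParams.
#' @return data.frame (n_active, x, m, probability).
#' @export
specificity_grid <- function(n_active_values = c(10, 25, 50, 100, 200),
                             x_values = 1:15, m_values = 0,
                             p = occupancy_params()) {
  g <- expand.grid(n_active = n_active_values, x = x_values, m = m_values)
  g$probability <- mapply(function(n, x, m) {
    if (m == 0) poisson_tail(n, x, p) else mr_adjusted_probability(n, x, m, p)
  }, g$n_active, g$x, g$m)
  g
}

#' Master-regulator-constrained multimer hit grid (heatmap data)
#'
#' Expected genome-wide k-TF multimer hits as a function of the number of
#' expressed TFs and the number of obligatory master regulators.
#'
#' @param k_values motif arities (default 4 and 5).
#' @param n_values numbers of expressed TFs.
#' @param m_values master-regulator counts (0 = absence of MR).
#' @param p OccupancyParams.
#' @return data.frame (k, n_tf, m, expected_hits, in_band).
#' @export
mr_hit_grid <- function(k_values = c(4, 5),
                        n_values = seq(100, 1600, by = 100),
                        m_values = c(0, 5, 10, 20),
                        p = occupancy_params()) {
  g <- expand.grid(k = k_values, n_tf = n_values, m = m_values)
  g$expected_hits <- mapply(function(k, n, m) {
    pn <- p
    pn$n_tf <- n
    mr_total_hit_expectation(pn, k, m)
  }, g$k, g$n_tf, g$m)
  g$in_band <- g$expected_hits >= p$active_band[1] &
    g$expected_hits <= p$active_band[2]
  g
}
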