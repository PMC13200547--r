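#' Configuration for the synthetic genotype/phenotype simulator
#'
#' Describes a simulated SNP study: `n` individuals genotyped at `p` markers
#' with dosages in \{0, 1, 2\}, per-marker minor-allele frequencies drawn
#' uniformly from `maf_range`, adjacent-marker linkage disequilibrium induced
#' by latent AR(1) Gaussian haplotype chains with correlation `ld_rho`, a
#' sparse additive genetic architecture with `k_causal` nonzero effects
#' (plus optional pairwise epistasis among causal markers), and Gaussian
#' noise scaled to a target narrow-sense heritability `h2`. Identical
#' configurations (including `seed`) reproduce identical data bit for bit.
#'
#' @param n Number of individuals.
#' @param p Number of markers.
#' @param maf_range Length-2 vector inside (0, 0.5]; per-marker MAFs are
#'   drawn uniformly from it.
#' @param ld_rho Latent adjacent-marker correlation in `[0, 1)`.
#' @param k_causal Number of markers with nonzero additive effects
#'   (`<= p`).
#' @param effect_sd Scale of the causal effects.
#' @param effect_dist `"normal"` draws effects from N(0, effect_sd^2);
#'   `"rademacher"` fixes them at +/- `effect_sd` with random signs.
#' @param n_epistatic_pairs Number of pairwise interaction terms among the
#'   causal markers (0 for a purely additive trait).
#' @param h2 Target heritability in `[0, 1]`: the noise variance is set from
#'   the realized genetic variance so that var(g)/var(y) targets `h2`.
#'   Ignored when `noise_sd` is given.
#' @param noise_sd Optional fixed noise standard deviation overriding the
#'   `h2` calibration.
#' @param seed Integer seed; the single source of randomness.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n, p, maf_range = c(0.05, 0.5), ld_rho = 0.3,
                       k_causal = 10L, effect_sd = 1, effect_dist = "normal",
                       n_epistatic_pairs = 0L, h2 = 0.5, noise_sd = NULL,
                       seed = 1L) {
  stopifnot(n >= 1, p >= 1, k_causal >= 0, k_causal <= p,
            n_epistatic_pairs >= 0, effect_sd > 0)
  effect_dist <- match.arg(effect_dist, c("normal", "rademacher"))
  if (length(maf_range) != 2L || maf_range[1L] > maf_range[2L] ||
      maf_range[1L] <= 0 || maf_range[2L] > 0.5)
    stop("`maf_range` must be (low, high) inside (0, 0.5]")
  if (ld_rho < 0 || ld_rho >= 1) stop("`ld_rho` must be in [0, 1)")
  if (is.null(noise_sd) && (h2 < 0 || h2 > 1)) stop("`h2` must be in [0, 1]")
  structure(list(n = as.integer(n), p = as.integer(p), maf_range = maf_range,
                 ld_rho = ld_rho, k_causal = as.integer(k_causal),
                 effect_sd = effect_sd, effect_dist = effect_dist,
                 n_epistatic_pairs = as.integer(n_epistatic_pairs),
                 h2 = h2, noise_sd = noise_sd, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a genotype matrix with linkage disequilibrium
#'
#' For each marker j a MAF is drawn from `maf_range`; two latent Gaussian
#' haplotype chains with AR(1) correlation `ld_rho` across adjacent markers
#' are thresholded at the MAF quantile (allele carried where the latent value
#' falls below `qnorm(maf)`) and summed, giving dosages in \{0, 1, 2\} whose
#' column means approximate `2 * MAF` and whose adjacent columns are
#' correlated.
#'
#' @param cfg A [sim_config()].
#' @return An n x p integer matrix with `sample_ids` rownames (`ind...`) and
#'   `marker_ids` colnames (`snp...`); attribute `"maf"` stores the drawn
#'   frequencies.
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    maf <- stats::runif(cfg$p, cfg$maf_range[1L], cfg$maf_range[2L])
    thr <- stats::qnorm(maf)
    G <- matrix(0L, cfg$n, cfg$p)
    for (h in 1:2) {
      Z <- matrix(stats::rnorm(cfg$n * cfg$p), cfg$n, cfg$p)
      if (cfg$ld_rho > 0 && cfg$p > 1L) {
        rho <- cfg$ld_rho
        w <- sqrt(1 - rho^2)
        for (j in 2:cfg$p) Z[, j] <- rho * Z[, j - 1L] + w * Z[, j]
      }
      G <- G + (Z < rep(thr, each = cfg$n))
    }
    storage.mode(G) <- "integer"
    dimnames(G) <- list(paste0("ind", seq_len(cfg$n)),
                        paste0("snp", seq_len(cfg$p)))
    attr(G, "maf") <- maf
    G
  })
}

#' Simulate a phenotype with known sparse genetic architecture
#'
#' Draws `k_causal` causal markers and their additive effects, builds the
#' genetic value \eqn{g_i = \sum_j \beta_j x_{ij}} (plus optional epistatic
#' products of standardized causal-pair dosages), adds Gaussian noise whose
#' variance is set from the realized var(g) so that var(g)/var(y) targets
#' `h2` (or uses `noise_sd` directly), and returns the phenotype standardized
#' to zero mean and unit variance together with the generating truth.
#'
#' @param G Genotype matrix from [simulate_genotypes()].
#' @param cfg The same [sim_config()] (its seed also fixes effects/noise;
#'   an offset keeps the genotype and phenotype draws independent).
#' @return List with `y` (standardized phenotype), and `truth`: `causal`
#'   (marker indices), `beta` (effects), `epistatic_pairs`, `g` (genetic
#'   values on the original scale), `realized_h2`, and the standardization
#'   (`center`, `scale`) mapping raw to returned phenotype.
#' @export
simulate_phenotype <- function(G, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- nrow(G); p <- ncol(G)
  if (cfg$k_causal == 0L && is.null(cfg$noise_sd) && cfg$h2 > 0)
    stop("h2 > 0 with no causal markers: scaling undefined")
  with_seed(cfg$seed + 1000003L, {
    causal <- if (cfg$k_causal > 0L) sort(sample.int(p, cfg$k_causal))
              else integer(0)
    beta <- switch(cfg$effect_dist,
      normal = stats::rnorm(cfg$k_causal, sd = cfg$effect_sd),
      rademacher = cfg$effect_sd * sample(c(-1, 1), cfg$k_causal,
                                          replace = TRUE))
    g <- if (cfg$k_causal > 0L)
      as.vector(G[, causal, drop = FALSE] %*% beta) else numeric(n)
    pairs <- NULL
    if (cfg$n_epistatic_pairs > 0L) {
      if (cfg$k_causal < 2L) stop("epistasis requires at least 2 causal markers")
      pairs <- t(replicate(cfg$n_epistatic_pairs,
                           sample(causal, 2L)))
      eff <- stats::rnorm(cfg$n_epistatic_pairs, sd = cfg$effect_sd)
      for (r in seq_len(cfg$n_epistatic_pairs)) {
        x1 <- scale(G[, pairs[r, 1L]])[, 1L]
        x2 <- scale(G[, pairs[r, 2L]])[, 1L]
        g <- g + eff[r] * x1 * x2
      }
      pairs <- cbind(pairs, effect = eff)
    }
    vg <- stats::var(g)
    sigma <- if (!is.null(cfg$noise_sd)) cfg$noise_sd
             else if (cfg$h2 == 1) 0
             else if (cfg$h2 == 0) 1
             else sqrt(vg * (1 - cfg$h2) / cfg$h2)
    if (cfg$h2 == 1 && vg == 0)
      stop("h2 = 1 with zero genetic variance: scaling undefined")
    e <- stats::rnorm(n, sd = sigma)
    # h2 = 0 means no heritable variance: the phenotype is pure noise
    y_raw <- if (is.null(cfg$noise_sd) && cfg$h2 == 0) e else g + e
    ctr <- mean(y_raw)
    scl <- stats::sd(y_raw)
    if (scl == 0) scl <- 1
    y <- (y_raw - ctr) / scl
    genetic_in_y <- !(is.null(cfg$noise_sd) && cfg$h2 == 0)
    realized <- if (vg > 0 && genetic_in_y) vg / stats::var(y_raw) else 0
    list(y = stats::setNames(y, rownames(G)),
         truth = list(causal = causal, beta = beta, epistatic_pairs = pairs,
                      g = g, realized_h2 = realized,
                      center = ctr, scale = scl))
  })
}

#' Simulate a complete genotype/phenotype dataset
#'
#' Convenience wrapper running [simulate_genotypes()] and
#' [simulate_phenotype()] for one configuration.
#'
#' @param cfg A [sim_config()].
#' @return List with `G`, `y`, `truth`, and `cfg`.
#' @export
simulate_dataset <- function(cfg) {
  G <- simulate_genotypes(cfg)
  ph <- simulate_phenotype(G, cfg)
  list(G = G, y = ph$y, truth = ph$truth, cfg = cfg)
}
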