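#' Simulation configuration
#'
#' Describes one synthetic-phenotype setting under the linear mixed model
#' `y = X beta + u + eps`: `n_samples` individuals, `n_causal` causal
#' markers whose target variance fractions are `causal_fractions` (fixed
#' values, or a sampling rule `list(mean=, sd=)` giving
#' `c_i ~ N(mean, sd^2)/100` truncated positive), an optional pairwise
#' multiplicative (Hadamard) interaction between the first two causal
#' markers, Gaussian or mean-centred gamma noise, and a background
#' heritability `h` that fixes the noise variance via
#' `sigma^2 = (1 - h)/h * Var(u)`.
#'
#' @param name configuration label.
#' @param n_samples number of individuals drawn from the genotype panel.
#' @param n_causal number of additive causal markers (0 allowed for a
#'   background-only trait).
#' @param causal_fractions numeric vector of length `n_causal` with target
#'   variance fractions, or `list(mean=, sd=)` for the sampled-percentage
#'   rule.
#' @param interaction optional `list(fraction=)`: adds a Hadamard-product
#'   term between the first two causal markers with that target fraction.
#' @param noise_family `"gaussian"` or `"gamma"`.
#' @param gamma_shape shape parameter of the gamma noise (skewness
#'   `2/sqrt(shape)`); ignored for Gaussian noise.
#' @param heritability background heritability `h` in (0, 1).
#' @param n_background number of polygenic background markers (default 1000).
#' @param background_sd standard deviation of the background effects
#'   `gamma` (default 0.1).
#' @return A `gs_sim_config` object.
#' @export
sim_config <- function(name, n_samples, n_causal, causal_fractions,
                       interaction = NULL,
                       noise_family = c("gaussian", "gamma"),
                       gamma_shape = 1, heritability = 0.95,
                       n_background = 1000, background_sd = 0.1) {
  noise_family <- match.arg(noise_family)
  stopifnot(n_samples >= 2, n_causal >= 0,
            n_background >= 1, background_sd >= 0)
  if (heritability <= 0 || heritability >= 1)
    stop("heritability must be in (0, 1)", call. = FALSE)
  if (is.numeric(causal_fractions)) {
    if (length(causal_fractions) != n_causal)
      stop("need one causal fraction per causal marker", call. = FALSE)
    tot <- sum(causal_fractions) +
      if (!is.null(interaction)) interaction$fraction else 0
    if (tot >= 1)
      stop("target variance fractions must sum to < 1", call. = FALSE)
  } else if (!is.list(causal_fractions) ||
             is.null(causal_fractions$mean) || is.null(causal_fractions$sd)) {
    stop("causal_fractions must be numeric or list(mean=, sd=)", call. = FALSE)
  }
  if (!is.null(interaction)) {
    if (n_causal < 2)
      stop("interaction requires at least two causal markers", call. = FALSE)
    stopifnot(is.numeric(interaction$fraction),
              interaction$fraction > 0, interaction$fraction < 1)
  }
  if (noise_family == "gamma" && gamma_shape <= 0)
    stop("gamma_shape must be positive", call. = FALSE)
  structure(
    list(name = name, n_samples = n_samples, n_causal = n_causal,
         causal_fractions = causal_fractions, interaction = interaction,
         noise_family = noise_family, gamma_shape = gamma_shape,
         heritability = heritability, n_background = n_background,
         background_sd = background_sd),
    class = "gs_sim_config")
}

#' @export
print.gs_sim_config <- function(x, ...) {
  frac <- if (is.numeric(x$causal_fractions)) {
    paste0("c = ", paste(signif(unique(x$causal_fractions), 3), collapse = "/"))
  } else {
    sprintf("c_i ~ N(%g, %g^2)/100", x$causal_fractions$mean, x$causal_fractions$sd)
  }
  cat(sprintf("<gs_sim_config> %s: n=%d, k=%d, %s%s, %s noise, h=%.2f\n",
              x$name, x$n_samples, x$n_causal, frac,
              if (!is.null(x$interaction))
                sprintf(" + interaction c=%g", x$interaction$fraction) else "",
              x$noise_family, x$heritability))
  invisible(x)
}

#' Built-in simulation grid
#'
#' The twelve named configurations A..L — growing sample sizes (A #100,
#' B #500, C #1000, D #2000), weak/strong multiplicative epistasis
#' (E, F), weakly/strongly skewed gamma noise (G shape 4, H shape 1), and
#' 5/20/50/100 additive causal markers with sampled percentage fractions
#' (I..L) — crossed with heritabilities 0.7, 0.85 and 0.95; 36
#' configurations in total. Entries are named `"<letter>_h<h>"`.
#'
#' @param heritabilities heritability grid (default `c(0.7, 0.85, 0.95)`).
#' @return Named list of `gs_sim_config` objects.
#' @export
builtin_configs <- function(heritabilities = c(0.7, 0.85, 0.95)) {
  base <- list(
    A = list(n = 100,  k = 1,  c = 0.3),
    B = list(n = 500,  k = 1,  c = 0.3),
    C = list(n = 1000, k = 1,  c = 0.3),
    D = list(n = 2000, k = 1,  c = 0.3),
    E = list(n = 1000, k = 2,  c = c(0.05, 0.05), int = 0.2),
    F = list(n = 1000, k = 2,  c = c(0.01, 0.01), int = 0.28),
    G = list(n = 1000, k = 1,  c = 0.3, noise = "gamma", shape = 4),
    H = list(n = 1000, k = 1,  c = 0.3, noise = "gamma", shape = 1),
    I = list(n = 1000, k = 5,   rule = list(mean = 6,   sd = 2)),
    J = list(n = 1000, k = 20,  rule = list(mean = 1.5, sd = 0.5)),
    K = list(n = 1000, k = 50,  rule = list(mean = 0.6, sd = 0.2)),
    L = list(n = 1000, k = 100, rule = list(mean = 0.3, sd = 0.1)))
  out <- list()
  for (h in heritabilities) {
    for (nm in names(base)) {
      b <- base[[nm]]
      cfg <- sim_config(
        name = sprintf("%s_h%g", nm, h),
        n_samples = b$n, n_causal = b$k,
        causal_fractions = if (!is.null(b$rule)) b$rule else b$c,
        interaction = if (!is.null(b$int)) list(fraction = b$int),
        noise_family = if (!is.null(b$noise)) b$noise else "gaussian",
        gamma_shape = if (!is.null(b$shape)) b$shape else 1,
        heritability = h)
      out[[cfg$name]] <- cfg
    }
  }
  out
}

#' Sample the polygenic background
#'
#' Selects `n_background` markers uniformly without replacement, draws
#' their effects `gamma ~ N(0, sd^2)` i.i.d., and returns the per-sample
#' polygenic value `u = Z gamma` with `Z` the additive 0/1/2 columns.
#'
#' @param G a `gs_genotypes` object (already subset to the simulated samples).
#' @param n_background number of background markers.
#' @param sd standard deviation of the background effects.
#' @return list with `background_indices`, `gamma`, `u`.
#' @export
sample_background <- function(G, n_background = 1000, sd = 0.1) {
  stopifnot(inherits(G, "gs_genotypes"))
  m <- ncol(G$values)
  if (n_background > m)
    stop("n_background exceeds the number of markers", call. = FALSE)
  idx <- sort(sample.int(m, n_background))
  gamma <- stats::rnorm(n_background, 0, sd)
  u <- as.numeric(G$values[, idx, drop = FALSE] %*% gamma)
  list(background_indices = idx, gamma = gamma, u = u)
}

#' Noise variance implied by the background heritability
#'
#' `sigma^2 = (1 - h)/h * Var(u)`: the polygenic term explains a fraction
#' `h` of the background phenotypic variance `Var(u) + sigma^2`.
#'
#' @param h heritability in (0, 1).
#' @param var_u variance of the polygenic values.
#' @export
noise_variance <- function(h, var_u) {
  if (!is.numeric(h) || length(h) != 1 || h <= 0 || h >= 1)
    stop("h must be in (0, 1)", call. = FALSE)
  stopifnot(var_u >= 0)
  (1 - h) / h * var_u
}

#' Draw mean-centred noise
#'
#' Gaussian: `N(0, sigma2)`. Gamma: `Gamma(shape, scale = sqrt(sigma2/shape))`
#' minus its mean, so the variance is `sigma2` and the skewness
#' `2/sqrt(shape)` is positive; smaller shapes give stronger skew.
#'
#' @param family `"gaussian"` or `"gamma"`.
#' @param sigma2 target variance (> 0).
#' @param gamma_shape gamma shape parameter (> 0).
#' @param n number of draws.
#' @export
draw_noise <- function(family = c("gaussian", "gamma"), sigma2,
                       gamma_shape = 1, n) {
  family <- match.arg(family)
  if (!is.numeric(sigma2) || sigma2 <= 0)
    stop("sigma2 must be positive", call. = FALSE)
  if (family == "gaussian") {
    stats::rnorm(n, 0, sqrt(sigma2))
  } else {
    if (gamma_shape <= 0) stop("gamma_shape must be positive", call. = FALSE)
    scale <- sqrt(sigma2 / gamma_shape)
    stats::rgamma(n, shape = gamma_shape, scale = scale) - gamma_shape * scale
  }
}

#' Effect size for a target variance fraction
#'
#' `beta = sqrt((c / (1 - c_total)) * var_background_pheno / var_x)`, where
#' `var_background_pheno = Var(u + eps)` is the variance of the phenotype
#' *before* fixed effects are added and `c_total` is the summed target
#' share of *all* fixed effects (every built-in configuration sums to 0.3).
#' Under mutual independence of the causal columns and the background, each
#' added term `beta * x` then contributes exactly its fraction `c` of the
#' total variance: the terms jointly add `c_total/(1 - c_total) * Var(u+eps)`,
#' so the total variance is `Var(u+eps)/(1 - c_total)` and the share of
#' term i is `c_i`. With a single fixed effect `c_total = c` and the
#' formula reduces to the familiar `c/(1-c)` sizing.
#'
#' @param c target variance fraction of this effect, in (0, 1).
#' @param var_background_pheno variance of `u + eps`.
#' @param var_x variance of the causal marker (or interaction) column.
#' @param c_total summed target fraction of all fixed effects (default `c`).
#' @export
effect_size <- function(c, var_background_pheno, var_x, c_total = c) {
  stopifnot(c > 0, c < 1, c_total >= c, c_total < 1,
            var_background_pheno >= 0)
  if (var_x <= 0)
    stop("causal column has zero variance", call. = FALSE)
  sqrt((c / (1 - c_total)) * var_background_pheno / var_x)
}

#' Simulate a phenotype on a genotype panel
#'
#' Realizes one configuration: draws `n_samples` rows without replacement,
#' builds the polygenic background, fixes the noise variance from the
#' empirical `Var(u)` and the heritability, draws the noise, then adds the
#' fixed effects. Causal markers are drawn disjoint from the background
#' set; each effect is sized against `Var(u + eps)` via [effect_size()].
#' An interaction term uses the Hadamard product of the first two causal
#' markers as its column. Markers (or products) that are constant within
#' the drawn sample set are resampled, up to a bounded retry count.
#' Fully reproducible from `seed`.
#'
#' @param config a `gs_sim_config`.
#' @param G a `gs_genotypes` panel with at least `n_samples` rows.
#' @param seed integer seed.
#' @return A `gs_phenotype` object: list with `y` (named by sample id),
#'   `config`, `seed`, `sample_ids`, `truth` (ground truth: background and
#'   causal indices, `gamma`, `beta`, `u`, `epsilon`, `sigma2`,
#'   per-term fixed-effect contributions) and `realized_fractions`.
#' @export
simulate_phenotype <- function(config, G, seed = 1L) {
  stopifnot(inherits(config, "gs_sim_config"), inherits(G, "gs_genotypes"))
  n_all <- nrow(G$values)
  if (config$n_samples > n_all)
    stop("config needs more samples than the panel provides", call. = FALSE)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  rows <- sort(sample.int(n_all, config$n_samples))
  Gs <- G[rows, ]
  n <- config$n_samples
  m <- ncol(Gs$values)

  bg <- sample_background(Gs, config$n_background, config$background_sd)
  u <- bg$u
  var_u <- stats::var(u)
  sigma2 <- noise_variance(config$heritability, var_u)
  eps <- if (sigma2 > 0) {
    draw_noise(config$noise_family, sigma2, config$gamma_shape, n)
  } else rep(0, n)
  var_bg_pheno <- stats::var(u + eps)

  # target fractions: fixed, or sampled percentages truncated positive
  fracs <- config$causal_fractions
  if (is.list(fracs)) {
    draw_frac <- function() {
      for (i in 1:1000) {
        v <- stats::rnorm(1, fracs$mean, fracs$sd) / 100
        if (v > 0) return(v)
      }
      stop("could not draw a positive variance fraction", call. = FALSE)
    }
    fracs <- vapply(seq_len(config$n_causal), function(i) draw_frac(), 0)
  }

  # causal markers: disjoint from the background, non-constant in sample
  pool <- setdiff(seq_len(m), bg$background_indices)
  causal <- integer(0)
  k <- config$n_causal
  if (k > 0) {
    if (length(pool) < k)
      stop("not enough non-background markers for the causal set", call. = FALSE)
    tries <- 0L
    while (length(causal) < k) {
      tries <- tries + 1L
      if (tries > 50L)
        stop("could not find non-constant causal markers", call. = FALSE)
      avail <- setdiff(pool, causal)
      cand <- avail[sample.int(length(avail), k - length(causal))]
      ok <- vapply(cand, function(j) stats::var(Gs$values[, j]) > 0, TRUE)
      causal <- c(causal, cand[ok])
    }
  }

  c_total <- sum(fracs) +
    if (!is.null(config$interaction)) config$interaction$fraction else 0

  terms <- list()
  beta <- numeric(0)
  if (k > 0) {
    for (i in seq_len(k)) {
      x <- as.numeric(Gs$values[, causal[i]])
      b <- effect_size(fracs[i], var_bg_pheno, stats::var(x), c_total)
      beta <- c(beta, b)
      terms[[paste0("causal_", i)]] <- b * x
    }
  }
  interaction_pair <- NULL
  if (!is.null(config$interaction)) {
    # Hadamard product of the first two causal markers; resample the pair
    # (keeping marker 1) if the product is constant in this sample set
    tries <- 0L
    repeat {
      tries <- tries + 1L
      xint <- as.numeric(Gs$values[, causal[1]] * Gs$values[, causal[2]])
      if (stats::var(xint) > 0) break
      if (tries > 50L)
        stop("interaction column constant after repeated resampling", call. = FALSE)
      avail <- setdiff(pool, causal)
      avail <- avail[vapply(avail, function(j) stats::var(Gs$values[, j]) > 0, TRUE)]
      causal[2] <- avail[sample.int(length(avail), 1)]
      x2 <- as.numeric(Gs$values[, causal[2]])
      beta[2] <- effect_size(fracs[2], var_bg_pheno, stats::var(x2), c_total)
      terms[["causal_2"]] <- beta[2] * x2
    }
    b_int <- effect_size(config$interaction$fraction, var_bg_pheno,
                         stats::var(xint), c_total)
    beta <- c(beta, b_int)
    interaction_pair <- causal[1:2]
    terms[["interaction"]] <- b_int * xint
  }

  fixed <- if (length(terms)) Reduce(`+`, terms) else rep(0, n)
  y <- fixed + u + eps
  names(y) <- Gs$sample_ids

  var_y <- stats::var(y)
  realized <- c(
    vapply(terms, function(t) stats::var(t) / var_y, 0),
    background = var_u / var_y,
    noise = stats::var(eps) / var_y)

  truth <- list(
    background_indices = bg$background_indices,
    background_markers = Gs$marker_ids[bg$background_indices],
    gamma = bg$gamma,
    causal_indices = causal,
    causal_markers = Gs$marker_ids[causal],
    beta = beta,
    interaction_pair = interaction_pair,
    target_fractions = c(fracs,
                         if (!is.null(config$interaction)) config$interaction$fraction),
    u = u, epsilon = eps, sigma2 = sigma2,
    fixed_terms = terms)

  structure(
    list(y = y, config = config, seed = as.integer(seed),
         sample_ids = Gs$sample_ids, sample_rows = rows,
         truth = truth, realized_fractions = realized),
    class = "gs_phenotype")
}

#' @export
print.gs_phenotype <- function(x, ...) {
  cat(sprintf("<gs_phenotype> %s, n=%d, seed=%d\n",
              x$config$name, length(x$y), x$seed))
  rf <- x$realized_fractions
  cat(sprintf("  realized: background %.3f, noise %.3f, fixed %.3f\n",
              rf[["background"]], rf[["noise"]],
              sum(rf) - rf[["background"]] - rf[["noise"]]))
  invisible(x)
}

#' Empirical variance decomposition of a simulated phenotype
#'
#' Returns the empirical variance of each fixed-effect term, the polygenic
#' value `u` and the noise, each divided by the empirical `Var(y)`, as a
#' tibble. The fractions sum to ~1 only up to sampling covariances between
#' components (they are uncorrelated in expectation, not in sample).
#'
#' @param sp a `gs_phenotype`.
#' @return tibble with columns `component`, `variance`, `fraction`.
#' @export
realized_variance_components <- function(sp) {
  stopifnot(inherits(sp, "gs_phenotype"))
  var_y <- stats::var(sp$y)
  comps <- c(sp$truth$fixed_terms,
             list(background = sp$truth$u, noise = sp$truth$epsilon))
  tibble::tibble(
    component = names(comps),
    variance = unname(vapply(comps, stats::var, 0)),
    fraction = unname(vapply(comps, function(v) stats::var(v) / var_y, 0)))
}

#' Serialize / restore the ground truth of a simulated phenotype
#'
#' The sidecar is JSON: a config echo, seed, indices, effects and noise
#' variance — everything needed to rescore importances against the truth.
#'
#' @param sp a `gs_phenotype`.
#' @param path output path (`.json`).
#' @export
write_truth_json <- function(sp, path) {
  stopifnot(inherits(sp, "gs_phenotype"))
  cfg <- sp$config
  obj <- list(
    config = list(name = cfg$name, n_samples = cfg$n_samples,
                  n_causal = cfg$n_causal,
                  heritability = cfg$heritability,
                  noise_family = cfg$noise_family,
                  gamma_shape = cfg$gamma_shape,
                  n_background = cfg$n_background,
                  background_sd = cfg$background_sd),
    seed = sp$seed,
    sample_ids = sp$sample_ids,
    background_markers = sp$truth$background_markers,
    gamma = sp$truth$gamma,
    causal_markers = sp$truth$causal_markers,
    beta = sp$truth$beta,
    target_fractions = sp$truth$target_fractions,
    sigma2 = sp$truth$sigma2)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
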