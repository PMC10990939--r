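# Measurement pipeline: normalization of fraction tables, pairwise and pool
# enrichment statistics, Soret-coefficient fitting against the forward
# chamber model, and the decomposition of replicate variability into
# systematic and random parts.

#' Construct / validate a fraction table
#'
#' A fraction table holds the per-fraction readout of frozen-and-cut chamber
#' experiments: one value per (species, replicate, fraction), in arbitrary
#' response units, plus the measured temperature difference of each
#' replicate. Fraction index 1 is the TOP slab.
#'
#' @param data data.frame with columns `species`, `replicate`,
#'   `fraction_index` (1 = top), `value` (>= 0) and `delta_T_K`.
#' @return the validated data.frame with class `fraction_table`.
#' @export
fraction_table <- function(data) {
  req <- c("species", "replicate", "fraction_index", "value", "delta_T_K")
  if (!all(req %in% names(data))) {
    stop("fraction table needs columns: ", paste(req, collapse = ", "))
  }
  if (any(data$value < 0)) stop("fraction values must be >= 0")
  if (any(!is.finite(data$value))) stop("fraction values must be finite")
  # delta_T must be constant within a replicate
  agg <- stats::aggregate(delta_T_K ~ replicate, data,
                          function(v) diff(range(v)))
  if (any(agg$delta_T_K > 1e-9)) {
    stop("delta_T_K must be constant within each replicate")
  }
  class(data) <- unique(c("fraction_table", class(data)))
  data
}

#' Normalize a fraction table to per-replicate chamber mean 1
#'
#' Divides every raw value by the mean over fractions of its (species,
#' replicate) group, so each species in each replicate has mean 1 across
#' fractions. This removes calibration factors and absolute concentrations:
#' multiplying a species' raw values by any constant leaves the result
#' unchanged. The operation is idempotent.
#'
#' @param table a [fraction_table()].
#' @return a normalized `fraction_table`.
#' @export
normalize_fractions <- function(table) {
  table <- fraction_table(table)
  key <- interaction(table$species, table$replicate, drop = TRUE)
  mns <- tapply(table$value, key, mean)
  bad <- names(mns)[mns == 0]
  if (length(bad)) {
    stop("all-zero fraction values for species/replicate: ",
         paste(bad, collapse = ", "))
  }
  table$value <- table$value / as.numeric(mns[as.character(key)])
  attr(table, "normalized") <- TRUE
  table
}

resolve_fraction <- function(table, fraction) {
  nfr <- max(table$fraction_index)
  if (is.character(fraction)) {
    fraction <- switch(fraction, top = 1L, bottom = nfr,
                       stop("fraction must be 'top', 'bottom' or an index"))
  }
  if (!fraction %in% table$fraction_index) stop("fraction index not present")
  fraction
}

fraction_matrix <- function(table, fraction) {
  sub <- table[table$fraction_index == fraction, ]
  m <- tapply(sub$value, list(sub$species, sub$replicate), mean)
  if (anyNA(m)) stop("missing species/replicate combinations in fraction table")
  m
}

#' Pairwise enrichment matrix in one fraction
#'
#' For every ordered species pair (A, B) computes the replicate-mean of the
#' per-replicate concentration ratio minus 1,
#' \deqn{E_{AB} = \frac{1}{K}\sum_k \frac{[A]_{j,k}}{[B]_{j,k}} - 1,}
#' together with the s.d. over the per-replicate ratios. Ratios are averaged
#' only AFTER being formed per replicate: the temperature difference varies
#' slightly between replicates and shifts all species of a replicate
#' together, so averaging concentrations first would distort the enrichment.
#'
#' @param table a normalized [fraction_table()] (normalization is applied if
#'   missing).
#' @param fraction `"top"`, `"bottom"`, or a fraction index (1 = top).
#' @return an object of class `enrichment_matrix`: list with `mean` and `sd`
#'   species x species matrices (entry \[A, B\] is the enrichment of A over
#'   B), and `fraction`.
#' @export
pairwise_enrichment <- function(table, fraction = "bottom") {
  if (!isTRUE(attr(table, "normalized"))) table <- normalize_fractions(table)
  j <- resolve_fraction(table, fraction)
  m <- fraction_matrix(table, j)
  if (any(m == 0)) {
    stop("zero concentration in fraction ", j,
         " for some species/replicate: ratio undefined")
  }
  sp <- rownames(m); S <- length(sp)
  E <- SD <- matrix(0, S, S, dimnames = list(sp, sp))
  for (a in seq_len(S)) for (b in seq_len(S)) {
    if (a == b) next
    r <- m[a, ] / m[b, ]
    E[a, b] <- mean(r) - 1
    SD[a, b] <- stats::sd(r)
  }
  structure(list(mean = E, sd = SD, fraction = j),
            class = "enrichment_matrix")
}

#' Enrichment of each species relative to the pool mean in one fraction
#'
#' Computes, per replicate, the pool mean of the normalized concentrations of
#' all species in the fraction, then the replicate-mean of each species'
#' ratio to that pool mean, minus 1 (`form = "ratio"`, the default, which is
#' dimensionally consistent with the pairwise statistic). A literal
#' difference form, replicate-mean of `([A] - pool) - 1`, is available as
#' `form = "difference"` for comparison.
#'
#' @param table a [fraction_table()].
#' @param fraction `"top"`, `"bottom"` or an index.
#' @param form `"ratio"` (default) or `"difference"`.
#' @return data.frame with columns `species`, `enrichment`, `sd`.
#' @export
pool_enrichment <- function(table, fraction = "bottom",
                            form = c("ratio", "difference")) {
  form <- match.arg(form)
  if (!isTRUE(attr(table, "normalized"))) table <- normalize_fractions(table)
  j <- resolve_fraction(table, fraction)
  m <- fraction_matrix(table, j)
  if (nrow(m) < 2) stop("pool enrichment needs >= 2 species")
  pool <- colMeans(m)
  if (any(pool == 0)) stop("pool mean is zero in some replicate")
  per_rep <- switch(form,
    ratio = sweep(m, 2, pool, "/"),
    difference = sweep(m, 2, pool, "-") + 1)
  data.frame(species = rownames(m),
             enrichment = rowMeans(per_rep) - 1,
             sd = apply(per_rep, 1, stats::sd),
             row.names = NULL)
}

# forward model: fraction means after `duration` of accumulation
forward_fraction_means <- function(S_T, D, delta_T, geometry, settings,
                                   duration, T_hot) {
  th <- thermal_conditions(T_hot - delta_T, T_hot)
  sol <- solute("fit", D, S_T)
  flow <- convective_flow_field(geometry, th, settings = settings)
  fld <- solve_drift_diffusion(flow, sol, mode = "transient",
                               duration = duration)
  fraction_averages(fld, geometry$n_fractions)
}

#' Fit Soret coefficients from measured fraction tables
#'
#' For each species and replicate, finds the Soret coefficient whose forward
#' transport simulation (transient accumulation over `duration` in the given
#' chamber geometry, at the replicate's measured temperature difference) best
#' matches the normalized measured fraction means, in the least-squares
#' sense. The one-dimensional objective is unimodal in `S_T`, so a bounded
#' golden-section search over `bounds` is used; an optimum within `1e-4` of a
#' bound is flagged. Per-species estimates are the mean over replicates, with
#' `sigma_random` the s.d. across replicate fits. When at least two species
#' and two replicates are available, the replicate correlation is decomposed
#' into a systematic and a random part via [replicate_error_split()].
#'
#' @param table a [fraction_table()].
#' @param geometry chamber geometry; the measurement chamber is 50 mm tall.
#' @param D diffusion coefficient assumption: single value or named vector
#'   per species (m^2 s^-1).
#' @param duration accumulation time in s (default 18 h).
#' @param bounds search interval for `S_T` (K^-1).
#' @param T_hot hot-wall temperature (degC); the cold wall sits at
#'   `T_hot - delta_T`.
#' @param settings solver settings for the forward model.
#' @param tol absolute tolerance on `S_T` for the search.
#' @return an object of class `soret_estimates`: data.frame with columns
#'   `species`, `S_T`, `sigma_random`, `sigma_systematic`, `n_replicates`,
#'   `at_boundary`; per-replicate fits in `attr(, "replicate_fits")`.
#' @export
fit_soret <- function(table, geometry = single_chamber_geometry(),
                      D = 1.4e-9, duration = 18 * 3600,
                      bounds = c(-1e-2, 2e-2), T_hot = 40,
                      settings = solver_settings(), tol = 2e-6) {
  table <- normalize_fractions(table)
  species <- sort(unique(as.character(table$species)))
  reps <- sort(unique(table$replicate))
  nfr <- max(table$fraction_index)
  if (length(D) > 1 && is.null(names(D))) {
    stop("per-species D must be a named vector")
  }
  fits <- matrix(NA_real_, length(species), length(reps),
                 dimnames = list(species, as.character(reps)))
  at_boundary <- logical(length(species))
  for (si in seq_along(species)) {
    sp <- species[si]
    Dsp <- if (length(D) == 1L) unname(D) else {
      if (!sp %in% names(D)) stop("no D supplied for species ", sp)
      unname(D[[sp]])
    }
    for (ri in seq_along(reps)) {
      sub <- table[table$species == sp & table$replicate == reps[ri], ]
      sub <- sub[order(sub$fraction_index), ]
      meas <- sub$value
      dT <- sub$delta_T_K[1]
      if (dT == 0 || max(abs(meas - 1)) < 1e-12) {
        fits[si, ri] <- 0
        next
      }
      obj <- function(st) {
        sum((forward_fraction_means(st, Dsp, dT, geometry, settings,
                                    duration, T_hot) - meas)^2)
      }
      opt <- stats::optimize(obj, interval = bounds, tol = tol)
      fits[si, ri] <- opt$minimum
      if (min(abs(opt$minimum - bounds)) < 1e-4) at_boundary[si] <- TRUE
    }
  }
  est <- data.frame(
    species = species,
    S_T = rowMeans(fits),
    sigma_random = if (length(reps) > 1) apply(fits, 1, stats::sd) else 0,
    sigma_systematic = NA_real_,
    n_replicates = length(reps),
    at_boundary = at_boundary,
    row.names = NULL)
  if (length(species) >= 2 && length(reps) >= 2) {
    split <- replicate_error_split(fits)
    est$sigma_systematic <- split$sigma_systematic
    # the regression-residual estimate supersedes the naive per-species s.d.
    est$sigma_random_regression <- split$sigma_random
  }
  attr(est, "replicate_fits") <- fits
  class(est) <- c("soret_estimates", class(est))
  est
}

#' Split replicate variability into systematic and random errors
#'
#' Replicate experiments differ slightly in their temperature difference
#' (1-2 K), which shifts the apparent Soret coefficients of ALL species of a
#' replicate together -- a multiplicative, systematic effect. For every
#' ordered replicate pair (A, B), the coefficients of replicate B are
#' regressed through the origin on those of replicate A across species: the
#' deviation of the slope from 1 measures the common multiplicative shift
#' (systematic error), while the scatter of the residuals measures the
#' per-species, per-replicate noise (random error). Both are averaged over
#' all ordered pairs; the residual s.d. is divided by sqrt(2) because both
#' coordinates of each point carry one replicate's worth of noise.
#'
#' @param fits species x replicates matrix of fitted Soret coefficients
#'   (K^-1), e.g. `attr(fit_soret(...), "replicate_fits")`.
#' @return list with `sigma_systematic` (fraction; mean |slope - 1| over
#'   ordered pairs), `sigma_random` (K^-1; per-replicate random error),
#'   `slopes` (per ordered pair) and `n_pairs`.
#' @export
replicate_error_split <- function(fits) {
  fits <- as.matrix(fits)
  if (nrow(fits) < 2) stop("need >= 2 species to define the regression slope")
  if (ncol(fits) < 2) stop("need >= 2 replicates")
  K <- ncol(fits)
  slopes <- numeric(0); rsd <- numeric(0)
  for (a in seq_len(K)) for (b in seq_len(K)) {
    if (a == b) next
    fit <- stats::lm(fits[, b] ~ 0 + fits[, a])
    slopes <- c(slopes, unname(stats::coef(fit)[1]))
    rsd <- c(rsd, sqrt(sum(stats::residuals(fit)^2) /
                         max(1L, nrow(fits) - 1L)))
  }
  list(sigma_systematic = mean(abs(slopes - 1)),
       sigma_random = mean(rsd) / sqrt(2),
       slopes = slopes,
       n_pairs = length(slopes))
}
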