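# Precomputed single-chamber responses on a parameter grid ("transfer
# table"): the building block of the network simulator. Axes: delta_T (K),
# D (m^2/s), S_T (1/K), Q_in (m^3/s), Q_out_bot (fraction of Q_in). Each cell
# stores the steady response of a chamber with unit inlet concentration.

#' Build a transfer table of steady single-chamber responses
#'
#' Runs the steady chamber solver over the Cartesian product of the five
#' parameter axes and stores, for each cell, the bottom-region mean, the two
#' outlet concentrations and the fraction means, all relative to a unit inlet
#' concentration. The table is the lookup the network simulator interpolates
#' instead of re-solving a chamber per network node.
#'
#' A `delta_T` of 0 yields the identity response (all concentrations 1)
#' without invoking the solver. With `cache` set, a previously saved table
#' with identical axes, geometry and settings is reloaded instead of rebuilt,
#' and a fresh build is saved there.
#'
#' @param geometry a [chamber_geometry()]; network chambers default to 0.2 m
#'   height.
#' @param axes named list with numeric vectors `delta_T`, `D`, `S_T`, `Q_in`,
#'   `Q_out_bot`; each must be strictly increasing.
#' @param T_film film temperature (degC) at which water properties are
#'   evaluated for every `delta_T` (walls at `T_film +/- delta_T/2`).
#' @param settings a [solver_settings()].
#' @param cache optional path to a JSON file used to persist / reload the
#'   table.
#' @return an object of class `transfer_table`.
#' @export
build_transfer_table <- function(geometry = network_chamber_geometry(),
                                 axes,
                                 T_film = 32.5,
                                 settings = solver_settings(),
                                 cache = NULL) {
  stopifnot(inherits(geometry, "chamber_geometry"))
  req <- c("delta_T", "D", "S_T", "Q_in", "Q_out_bot")
  if (!all(req %in% names(axes))) {
    stop("axes must contain: ", paste(req, collapse = ", "))
  }
  axes <- axes[req]
  for (nm in req) {
    v <- axes[[nm]]
    if (!is.numeric(v) || length(v) < 1 || is.unsorted(v, strictly = TRUE)) {
      stop(sprintf("axis '%s' must be strictly increasing", nm))
    }
  }
  if (any(axes$Q_in <= 0)) stop("Q_in axis values must be > 0")
  if (any(axes$Q_out_bot <= 0 | axes$Q_out_bot > 1)) {
    stop("Q_out_bot axis values must be in (0, 1]")
  }

  key <- list(axes = axes, geometry = unclass(geometry),
              settings = unclass(settings), T_film = T_film)
  if (!is.null(cache) && file.exists(cache)) {
    tab <- load_transfer_table(cache)
    if (identical(rapply(tab$key, as.numeric, how = "replace"),
                  rapply(key, as.numeric, how = "replace"))) {
      return(tab)
    }
    warning("cache file does not match requested table; rebuilding")
  }

  dims <- unname(vapply(axes, length, 1L))
  nfr <- geometry$n_fractions
  bottom_mean <- array(NA_real_, dims)
  c_out_top <- array(NA_real_, dims)
  c_out_bot <- array(NA_real_, dims)
  fraction_means <- array(NA_real_, c(nfr, dims))
  failed <- character(0)

  idx <- expand.grid(lapply(dims, seq_len))
  for (r in seq_len(nrow(idx))) {
    i <- as.integer(idx[r, ])
    dT <- axes$delta_T[i[1]]; D <- axes$D[i[2]]; ST <- axes$S_T[i[3]]
    Qi <- axes$Q_in[i[4]]; fb <- axes$Q_out_bot[i[5]]
    cell <- rbind(i)
    if (dT == 0) {
      bottom_mean[cell] <- 1; c_out_top[cell] <- 1; c_out_bot[cell] <- 1
      fraction_means[cbind(seq_len(nfr), cell[rep(1, nfr), , drop = FALSE])] <- 1
      next
    }
    resp <- tryCatch(
      compute_response(geometry, thermal_from_film(dT, T_film),
                       solute("cell", D, ST), Qi, fb, settings),
      error = function(e) e)
    if (inherits(resp, "error")) {
      failed <- c(failed, sprintf("cell %s: %s",
                                  paste(i, collapse = ","), conditionMessage(resp)))
      next
    }
    bottom_mean[cell] <- resp$bottom_mean
    c_out_top[cell] <- resp$c_out_top
    c_out_bot[cell] <- resp$c_out_bot
    fraction_means[cbind(seq_len(nfr), cell[rep(1, nfr), , drop = FALSE])] <-
      resp$fraction_means
  }
  if (length(failed)) {
    stop("transfer-table cells failed to solve:\n",
         paste(failed, collapse = "\n"))
  }

  tab <- structure(
    list(axes = axes, bottom_mean = bottom_mean, c_out_top = c_out_top,
         c_out_bot = c_out_bot, fraction_means = fraction_means,
         key = key, geometry = geometry, settings = settings,
         T_film = T_film, package_version = as.character(utils::packageVersion("thermotrap"))),
    class = "transfer_table")
  if (!is.null(cache)) save_transfer_table(tab, cache)
  tab
}

#' @export
print.transfer_table <- function(x, ...) {
  cat("transfer table with axes:\n")
  for (nm in names(x$axes)) {
    cat(sprintf("  %-10s (%d): %s\n", nm, length(x$axes[[nm]]),
                paste(signif(x$axes[[nm]], 4), collapse = ", ")))
  }
  cat(sprintf("  %d cells\n", length(x$bottom_mean)))
  invisible(x)
}

#' Save / load a transfer table as self-describing JSON
#'
#' @param table a `transfer_table`.
#' @param path file path.
#' @return `load_transfer_table` returns the table; `save_transfer_table`
#'   returns `path` invisibly.
#' @export
save_transfer_table <- function(table, path) {
  stopifnot(inherits(table, "transfer_table"))
  obj <- list(axes = table$axes,
              dims = dim(table$bottom_mean),
              bottom_mean = as.numeric(table$bottom_mean),
              c_out_top = as.numeric(table$c_out_top),
              c_out_bot = as.numeric(table$c_out_bot),
              fraction_means = as.numeric(table$fraction_means),
              key = table$key,
              T_film = table$T_film,
              package_version = table$package_version)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_transfer_table
#' @export
load_transfer_table <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dims <- as.integer(obj$dims)
  geometry <- do.call(chamber_geometry, as.list(obj$key$geometry))
  settings <- do.call(solver_settings, as.list(obj$key$settings))
  axes <- lapply(obj$axes, as.numeric)
  structure(
    list(axes = axes,
         bottom_mean = array(obj$bottom_mean, dims),
         c_out_top = array(obj$c_out_top, dims),
         c_out_bot = array(obj$c_out_bot, dims),
         fraction_means = array(obj$fraction_means, c(geometry$n_fractions, dims)),
         key = list(axes = axes, geometry = unclass(geometry),
                    settings = unclass(settings), T_film = as.numeric(obj$T_film)),
         geometry = geometry, settings = settings,
         T_film = as.numeric(obj$T_film),
         package_version = obj$package_version),
    class = "transfer_table")
}

# locate bracketing indices + weight on one axis; Q axes interpolate in log10
axis_locate <- function(ax, value, name, logscale, clamp) {
  n <- length(ax)
  lo <- ax[1]; hi <- ax[n]
  if (value < lo || value > hi) {
    if (!clamp) {
      stop(sprintf(
        "query %s = %g outside transfer-table hull [%g, %g]",
        name, value, lo, hi), call. = FALSE)
    }
    value <- min(max(value, lo), hi)
  }
  if (n == 1L) return(list(i0 = 1L, i1 = 1L, w = 0))
  i0 <- findInterval(value, ax, rightmost.closed = TRUE)
  i0 <- min(max(i0, 1L), n - 1L)
  x0 <- ax[i0]; x1 <- ax[i0 + 1]
  w <- if (logscale) (log10(value) - log10(x0)) / (log10(x1) - log10(x0))
       else (value - x0) / (x1 - x0)
  list(i0 = i0, i1 = i0 + 1L, w = w)
}

#' Interpolate a transfer table at an off-grid parameter point
#'
#' Multilinear interpolation on all five axes; the two flow axes (`Q_in`,
#' `Q_out_bot`) are interpolated in log10 space because chamber responses
#' vary smoothly with the logarithm of the flow. Queries outside the axis
#' hull raise an error naming the offending axis unless `clamp = TRUE`, in
#' which case the query is clamped to the hull (intended for exploratory
#' network runs and reported via a warning the first time).
#'
#' @param table a `transfer_table`.
#' @param delta_T,D,S_T,Q_in,Q_out_bot query coordinates (scalar each).
#' @param clamp clamp out-of-hull queries instead of erroring.
#' @return list with `bottom_mean`, `c_out_top`, `c_out_bot` and
#'   `fraction_means` (relative to unit inlet concentration).
#' @export
interpolate_transfer <- function(table, delta_T, D, S_T, Q_in, Q_out_bot,
                                 clamp = FALSE) {
  stopifnot(inherits(table, "transfer_table"))
  qs <- list(delta_T = delta_T, D = D, S_T = S_T,
             Q_in = Q_in, Q_out_bot = Q_out_bot)
  logax <- c(delta_T = FALSE, D = FALSE, S_T = FALSE,
             Q_in = TRUE, Q_out_bot = TRUE)
  loc <- mapply(function(nm, v) axis_locate(table$axes[[nm]], v, nm,
                                            logax[[nm]], clamp),
                names(qs), qs, SIMPLIFY = FALSE)
  corners <- expand.grid(lapply(loc, function(l) c(0L, 1L)))
  out <- list(bottom_mean = 0, c_out_top = 0, c_out_bot = 0,
              fraction_means = numeric(dim(table$fraction_means)[1]))
  for (r in seq_len(nrow(corners))) {
    w <- 1; idx <- integer(5)
    for (a in seq_len(5)) {
      l <- loc[[a]]
      if (corners[r, a] == 0L) { idx[a] <- l$i0; w <- w * (1 - l$w) }
      else { idx[a] <- l$i1; w <- w * l$w }
    }
    if (w == 0) next
    cell <- rbind(idx)
    out$bottom_mean <- out$bottom_mean + w * table$bottom_mean[cell]
    out$c_out_top <- out$c_out_top + w * table$c_out_top[cell]
    out$c_out_bot <- out$c_out_bot + w * table$c_out_bot[cell]
    nfr <- dim(table$fraction_means)[1]
    out$fraction_means <- out$fraction_means +
      w * table$fraction_means[cbind(seq_len(nfr),
                                     cell[rep(1, nfr), , drop = FALSE])]
  }
  out
}
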