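# Stochastic model of interconnected heat-flow chambers. Chambers sit on an
# N_y (rows) x N_x (columns) grid; water flows strictly left to right, each
# chamber's outflow channels feeding chambers of the next column in the same
# row or one row above/below. Concentrations propagate column by column via
# interpolated single-chamber transfer responses.

#' Generate a random crack-network topology
#'
#' Chambers are arranged in `N_y` rows and `N_x` columns. Every first-column
#' chamber is fed by one boundary inlet at `Q_in`. Each chamber is assigned
#' one or two outflow channels (two with probability 1/2, feasibility
#' permitting); a channel from row m may only target rows m-1, m, m+1 of the
#' next column, and last-column channels exit through the boundary. After the
#' random assignment, any next-column chamber left without a feed is
#' repaired by adding a channel from a feasible upstream chamber that still
#' has spare outflow capacity, so every chamber receives at least one inflow
#' (a chamber may receive up to three). Chambers with two outflows never
#' target the same chamber twice. Each chamber's outflow ports are assigned
#' randomly: with two channels, one is designated the bottom-outlet channel;
#' with one channel, the port is top or bottom with equal probability.
#'
#' The construction is a pure function of `(N_x, N_y, seed)`.
#'
#' @param N_x number of columns (flow direction).
#' @param N_y number of rows.
#' @param Q_in boundary inlet flow rate per first-column chamber (m^3 s^-1);
#'   1 nl/s = 1e-12.
#' @param seed integer seed.
#' @return an object of class `network_topology` with a `channels`
#'   data.frame (`from_m`, `from_n`, `to_m`, `to_n`; `NA` target = boundary
#'   outlet; `port` is `"top"` or `"bottom"`).
#' @export
generate_topology <- function(N_x, N_y, Q_in = 1e-12, seed = 1L) {
  stopifnot(N_x >= 1, N_y >= 1)
  assert_number(Q_in, "Q_in", 0, Inf, strict = TRUE)
  with_seed(derive_seed(seed, 101L), {
    from_m <- integer(0); from_n <- integer(0)
    to_m <- integer(0); to_n <- integer(0)
    for (n in seq_len(N_x)) {
      ndeg <- 1L + stats::rbinom(N_y, 1L, 0.5)
      if (n == N_x) {
        # boundary outlets
        for (m in seq_len(N_y)) {
          k <- ndeg[m]
          from_m <- c(from_m, rep(m, k)); from_n <- c(from_n, rep(n, k))
          to_m <- c(to_m, rep(NA_integer_, k)); to_n <- c(to_n, rep(NA_integer_, k))
        }
        next
      }
      tgt <- vector("list", N_y)
      for (m in seq_len(N_y)) {
        feas <- intersect((m - 1L):(m + 1L), seq_len(N_y))
        k <- min(ndeg[m], length(feas))
        tgt[[m]] <- if (length(feas) == 1L) feas else
          sample(feas, k, replace = FALSE)
      }
      # repair: every next-column chamber needs >= 1 feed
      covered <- sort(unique(unlist(tgt)))
      for (m2 in setdiff(seq_len(N_y), covered)) {
        srcs <- intersect((m2 - 1L):(m2 + 1L), seq_len(N_y))
        spare <- srcs[vapply(srcs, function(sm) length(tgt[[sm]]) < 2L, TRUE)]
        if (length(spare)) {
          sm <- if (length(spare) == 1L) spare else sample(spare, 1L)
          tgt[[sm]] <- c(tgt[[sm]], m2)
        } else {
          # all feasible sources saturated: redirect one of their channels
          # whose current target has another feed
          done <- FALSE
          for (sm in sample(srcs)) {
            for (ti in seq_along(tgt[[sm]])) {
              t_old <- tgt[[sm]][ti]
              if (sum(unlist(tgt) == t_old) >= 2L) {
                tgt[[sm]][ti] <- m2; done <- TRUE; break
              }
            }
            if (done) break
          }
          if (!done) stop("internal error: topology repair failed")
        }
      }
      for (m in seq_len(N_y)) {
        k <- length(tgt[[m]])
        from_m <- c(from_m, rep(m, k)); from_n <- c(from_n, rep(n, k))
        to_m <- c(to_m, tgt[[m]]); to_n <- c(to_n, rep(n + 1L, k))
      }
    }
    channels <- data.frame(from_m = from_m, from_n = from_n,
                           to_m = to_m, to_n = to_n,
                           port = NA_character_)
    # port assignment per chamber
    for (n in seq_len(N_x)) for (m in seq_len(N_y)) {
      ch <- which(channels$from_m == m & channels$from_n == n)
      if (length(ch) == 2L) {
        bot <- sample(ch, 1L)
        channels$port[bot] <- "bottom"
        channels$port[setdiff(ch, bot)] <- "top"
      } else {
        channels$port[ch] <- sample(c("top", "bottom"), 1L)
      }
    }
    structure(list(N_x = as.integer(N_x), N_y = as.integer(N_y),
                   Q_in = Q_in, seed = as.integer(seed),
                   channels = channels),
              class = "network_topology")
  })
}

#' @export
print.network_topology <- function(x, ...) {
  cat(sprintf("crack network %d rows x %d columns, %d channels, seed %d\n",
              x$N_y, x$N_x, nrow(x$channels), x$seed))
  invisible(x)
}

#' Solve channel flow rates by solvent mass conservation
#'
#' Processes columns left to right. Each chamber's total outflow equals its
#' total inflow (water is incompressible and conserved). Where a chamber has
#' two outflow channels, the bottom channel's share of the flow is drawn
#' uniformly from `split_bounds` (seeded; a pure function of the topology
#' seed); with a single channel the full flow leaves through its port, so
#' the chamber's bottom-outflow fraction is 1 (bottom port) or 0 (top port).
#'
#' @param topology a [generate_topology()] result.
#' @param split_bounds bounds of the uniform two-outflow split ratio.
#' @return an object of class `network_flows`: the channel table with a
#'   `flow` column plus a per-chamber data.frame `chambers` with `Q_in` and
#'   `f_bot`.
#' @export
solve_flow_rates <- function(topology, split_bounds = c(0.1, 0.9)) {
  stopifnot(inherits(topology, "network_topology"))
  ch <- topology$channels
  N_x <- topology$N_x; N_y <- topology$N_y
  with_seed(derive_seed(topology$seed, 202L), {
    Qch <- rep(NA_real_, nrow(ch))
    Qin <- matrix(0, N_y, N_x)
    fbot <- matrix(NA_real_, N_y, N_x)
    Qin[, 1] <- topology$Q_in
    for (n in seq_len(N_x)) {
      for (m in seq_len(N_y)) {
        idx <- which(ch$from_m == m & ch$from_n == n)
        Q <- Qin[m, n]
        if (length(idx) == 2L) {
          f <- stats::runif(1, split_bounds[1], split_bounds[2])
          ib <- idx[ch$port[idx] == "bottom"]
          it <- idx[ch$port[idx] == "top"]
          Qch[ib] <- f * Q; Qch[it] <- (1 - f) * Q
          fbot[m, n] <- f
        } else {
          Qch[idx] <- Q
          fbot[m, n] <- if (ch$port[idx] == "bottom") 1 else 0
        }
      }
      if (n < N_x) {
        for (m2 in seq_len(N_y)) {
          feed <- which(ch$to_n == n + 1L & ch$to_m == m2)
          feed <- feed[!is.na(ch$to_m[feed])]
          Qin[m2, n + 1L] <- sum(Qch[feed])
        }
      }
    }
    ch$flow <- Qch
    chambers <- expand.grid(m = seq_len(N_y), n = seq_len(N_x))
    chambers$Q_in <- Qin[cbind(chambers$m, chambers$n)]
    chambers$f_bot <- fbot[cbind(chambers$m, chambers$n)]
    structure(list(channels = ch, chambers = chambers,
                   N_x = N_x, N_y = N_y, Q_inlet = topology$Q_in,
                   seed = topology$seed),
              class = "network_flows")
  })
}

#' Propagate solute concentrations through the network
#'
#' Processes columns left to right. Each chamber's inlet concentration is the
#' flow-weighted mixture of its feeding channels (boundary inlets carry the
#' feed concentration); its bottom and outlet concentrations are the inlet
#' concentration times the interpolated single-chamber transfer response at
#' the chamber's `(delta_T, D_i, S_T_i, Q_in, f_bot)`. Single-outflow
#' chambers with a top port have `f_bot = 0`, which lies outside the table
#' hull, so such queries are clamped to the smallest tabulated bottom
#' fraction; clamping elsewhere requires `clamp = TRUE`.
#'
#' @param topology a `network_topology`.
#' @param flows the matching [solve_flow_rates()] result.
#' @param solutes list of [solute()] objects (or a `data.frame` with columns
#'   `name`, `D`, `S_T`).
#' @param delta_T temperature difference applied to every chamber (K).
#' @param table a [build_transfer_table()] covering the query hull.
#' @param feed named vector of feed concentrations (default 1 per species).
#' @param clamp clamp out-of-hull interpolation queries (logged via warning).
#' @return an object of class `chamber_states`: data.frame with columns `m`,
#'   `n`, `species`, `c_in`, `c_bot`, `c_out_top`, `c_out_bot`.
#' @export
propagate <- function(topology, flows, solutes, delta_T, table,
                      feed = NULL, clamp = FALSE) {
  stopifnot(inherits(topology, "network_topology"),
            inherits(flows, "network_flows"),
            inherits(table, "transfer_table"))
  if (is.data.frame(solutes)) {
    solutes <- lapply(seq_len(nrow(solutes)), function(i) as_solute(solutes[i, ]))
  }
  if (inherits(solutes, "solute")) solutes <- list(solutes)
  spnames <- vapply(solutes, function(s) s$name, "")
  if (anyDuplicated(spnames)) stop("duplicate solute names")
  feed <- feed %||% stats::setNames(rep(1, length(solutes)), spnames)
  if (is.null(names(feed))) names(feed) <- spnames
  ch <- flows$channels
  N_x <- topology$N_x; N_y <- topology$N_y; S <- length(solutes)

  fb_min <- min(table$axes$Q_out_bot)
  c_channel <- matrix(NA_real_, nrow(ch), S)   # concentration carried per channel
  res <- array(NA_real_, c(N_y, N_x, S, 4),
               dimnames = list(NULL, NULL, spnames,
                               c("c_in", "c_bot", "c_out_top", "c_out_bot")))
  clamped <- FALSE
  for (n in seq_len(N_x)) {
    for (m in seq_len(N_y)) {
      Q <- flows$chambers$Q_in[flows$chambers$m == m & flows$chambers$n == n]
      fb <- flows$chambers$f_bot[flows$chambers$m == m & flows$chambers$n == n]
      if (n == 1L) {
        cin <- feed[spnames]
      } else {
        feedch <- which(ch$to_n == n & ch$to_m == m)
        w <- ch$flow[feedch]
        cin <- colSums(c_channel[feedch, , drop = FALSE] * w) / sum(w)
        names(cin) <- spnames
      }
      fb_q <- fb
      if (fb_q < fb_min) { fb_q <- fb_min; clamped <- TRUE }
      out <- which(ch$from_m == m & ch$from_n == n)
      for (si in seq_len(S)) {
        s <- solutes[[si]]
        r <- interpolate_transfer(table, delta_T, s$D, s$S_T, Q, fb_q,
                                  clamp = clamp)
        # project the interpolated outlet pair onto the exact solute flux
        # balance (1 - f) c_top + f c_bot = 1 at the chamber's physical
        # split: interpolation errors would otherwise compound
        # multiplicatively down the cascade (and a top-port-only chamber,
        # f = 0, must return its inlet concentration unchanged)
        bal <- (1 - fb) * r$c_out_top + fb * r$c_out_bot
        ctop <- r$c_out_top / bal
        cbot_out <- r$c_out_bot / bal
        res[m, n, si, ] <- c(cin[si], cin[si] * r$bottom_mean,
                             cin[si] * ctop, cin[si] * cbot_out)
        c_channel[out, si] <- ifelse(ch$port[out] == "bottom",
                                     cin[si] * cbot_out,
                                     cin[si] * ctop)
      }
    }
  }
  if (clamped) {
    message("note: top-port single-outflow chambers queried at the smallest ",
            "tabulated bottom-outflow fraction")
  }
  grid <- expand.grid(m = seq_len(N_y), n = seq_len(N_x),
                      species = spnames, stringsAsFactors = FALSE)
  grid$c_in <- res[cbind(grid$m, grid$n, match(grid$species, spnames), 1)]
  grid$c_bot <- res[cbind(grid$m, grid$n, match(grid$species, spnames), 2)]
  grid$c_out_top <- res[cbind(grid$m, grid$n, match(grid$species, spnames), 3)]
  grid$c_out_bot <- res[cbind(grid$m, grid$n, match(grid$species, spnames), 4)]
  structure(grid, class = c("chamber_states", class(grid)),
            N_x = N_x, N_y = N_y, delta_T = delta_T,
            channel_conc = c_channel, flows = flows)
}

#' Median-of-ten-maxima enrichment statistic
#'
#' Computes the per-chamber ratio of bottom concentrations of species A over
#' species B, takes the ten largest values and returns their median -- a
#' robust "maximum enrichment" statistic that is insensitive to a single
#' outlier chamber. With fewer than ten chambers, all are used.
#'
#' @param states a [propagate()] result (may pool chambers from several
#'   systems by `rbind`ing their rows).
#' @param A,B species names.
#' @param n_top number of largest ratios entering the median (default 10).
#' @return scalar fold-enrichment.
#' @export
max_enrichment <- function(states, A, B, n_top = 10L) {
  sa <- states[states$species == A, ]
  sb <- states[states$species == B, ]
  key <- paste(sa$m, sa$n)
  stopifnot(all(paste(sb$m, sb$n) == key))
  den <- sb$c_bot
  ok <- den > 0 & is.finite(den)
  if (any(!ok)) warning(sum(!ok), " chambers with zero denominator excluded")
  if (!any(ok)) stop("all chambers have zero denominator for species ", B)
  r <- sa$c_bot[ok] / den[ok]
  k <- min(n_top, length(r))
  stats::median(sort(r, decreasing = TRUE)[seq_len(k)])
}

#' Ensemble simulation with Soret-coefficient resampling
#'
#' Repeats the network simulation `repeats` times; in each repeat every
#' species' Soret coefficient is drawn from a Gaussian centred on its mean
#' value with s.d. `sigma_random`, and `Z` independent network topologies are
#' generated, propagated and pooled. The max-enrichment statistic of every
#' requested ordered species pair is computed per repeat on the pooled
#' chambers, and its mean and s.d. across repeats are returned, propagating
#' the measurement uncertainty of the Soret coefficients into the enrichment
#' predictions. Resampled coefficients are truncated to the transfer-table
#' hull.
#'
#' @param solutes list of [solute()] (with `sigma_random` fields) or a
#'   data.frame.
#' @param delta_T chamber temperature difference (K).
#' @param N_x,N_y network size.
#' @param Z number of network topologies per repeat.
#' @param repeats number of ensemble repeats.
#' @param table transfer table covering the hull.
#' @param Q_in boundary inlet flow per first-column chamber (m^3 s^-1).
#' @param pairs optional 2-column character matrix of (A, B) pairs; default
#'   all ordered pairs.
#' @param seed integer seed; the run is a pure function of it.
#' @param clamp clamp out-of-hull transfer queries (useful because summed
#'   network flows can exceed the tabulated `Q_in` range).
#' @param resample_topologies if `TRUE` (default) each repeat draws fresh
#'   topologies, so the reported s.d. contains both topology and
#'   Soret-sampling variability; with `FALSE` the same `Z` topologies are
#'   reused across repeats, isolating the Soret-coefficient uncertainty.
#' @return an object of class `ensemble_result`: data.frame with columns
#'   `A`, `B`, `mean`, `sd`, `n_repeats`; per-repeat values in
#'   `attr(, "per_repeat")`.
#' @export
ensemble <- function(solutes, delta_T, N_x, N_y, Z = 5L, repeats = 3L,
                     table, Q_in = 1e-12, pairs = NULL, seed = 1L,
                     clamp = TRUE, resample_topologies = TRUE) {
  if (is.data.frame(solutes)) {
    solutes <- lapply(seq_len(nrow(solutes)), function(i) as_solute(solutes[i, ]))
  }
  spnames <- vapply(solutes, function(s) s$name, "")
  if (is.null(pairs)) {
    pairs <- as.matrix(expand.grid(A = spnames, B = spnames,
                                   stringsAsFactors = FALSE))
    pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  }
  st_lo <- min(table$axes$S_T); st_hi <- max(table$axes$S_T)
  per <- matrix(NA_real_, nrow(pairs), repeats)
  failures <- character(0)
  for (r in seq_len(repeats)) {
    draw <- with_seed(derive_seed(seed, 303L, r), {
      vapply(solutes, function(s) {
        stats::rnorm(1, s$S_T, s$sigma_random)
      }, 0)
    })
    draw <- pmin(pmax(draw, st_lo), st_hi)
    sol_r <- mapply(function(s, st) solute(s$name, s$D, st),
                    solutes, draw, SIMPLIFY = FALSE)
    pooled <- NULL
    for (z in seq_len(Z)) {
      res <- tryCatch({
        topo <- generate_topology(
          N_x, N_y, Q_in,
          seed = derive_seed(seed, 404L, if (resample_topologies) r else 0L, z))
        fl <- solve_flow_rates(topo)
        suppressMessages(
          propagate(topo, fl, sol_r, delta_T, table, clamp = clamp))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures <- c(failures,
                      sprintf("repeat %d system %d: %s", r, z,
                              conditionMessage(res)))
        next
      }
      pooled <- if (is.null(pooled)) res else rbind(pooled, res)
    }
    if (is.null(pooled)) next
    for (p in seq_len(nrow(pairs))) {
      per[p, r] <- max_enrichment(pooled, pairs[p, 1], pairs[p, 2])
    }
  }
  out <- data.frame(A = pairs[, 1], B = pairs[, 2],
                    mean = rowMeans(per, na.rm = TRUE),
                    sd = apply(per, 1, stats::sd, na.rm = TRUE),
                    n_repeats = rowSums(!is.na(per)),
                    row.names = NULL)
  structure(out, class = c("ensemble_result", class(out)),
            per_repeat = per, failures = failures,
            settings = list(delta_T = delta_T, N_x = N_x, N_y = N_y,
                            Z = Z, repeats = repeats, seed = seed,
                            Q_in = Q_in))
}
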