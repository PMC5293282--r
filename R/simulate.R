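# Factory-model cell-cycle simulator.
#
# Each founder seeds an independent lineage ("field of view").  Cells
# elongate exponentially, L(t) = L0*exp(t/t0), and divide near midcell when
# they reach a noisy length threshold.  One replication round runs per
# division cycle: a fork pair appears at midcell at initiation, performs
# confined mean-reverting motion about its home position, transiently
# fissions into two resolved sister foci (two-state Markov chain with
# stationary resolved probability p_resolved), and disappears at
# termination.  After a D-period gap the two daughter rounds initiate --
# before division (near the quarter-cell positions, homes 0.5 +/-
# quarter_offset) with probability p_preinit, otherwise at the daughters'
# midcells after division.  Quarter-cell pairs persist through division;
# midcell pairs always vanish before it.

## A "resolved" pair is operationally a pair separated beyond the
## diffraction limit (otherwise it renders as one focus and is co-localized
## by definition), and the resolved-sister and quarter-cell separation
## populations are well resolved from each other.  Episode separations are
## therefore floored at 0.30 um relative to the current cell length --
## safely above the practical two-point resolution of the detection chain
## (2 sigma of the smoothed PSF ~ 255 nm noiseless, ~270-280 nm with shot
## noise) -- and capped at 0.30 cell lengths, below the 0.33 bound.
SEP_TRUNC_HI <- 0.30
SEP_MIN_UM <- 0.30

draw_sep <- function(cfg, L_um) {
  lo <- min(SEP_MIN_UM / L_um, SEP_TRUNC_HI - 0.02)
  rtnorm(1, cfg$resolved_sep_mean, cfg$resolved_sep_sd, lo, SEP_TRUNC_HI)
}

## ancestor chain root -> cell, used for group (chaining) computation
ancestor_chain <- function(uid, parent_of) {
  chain <- uid
  while (!is.na(parent_of[chain[1]])) chain <- c(parent_of[chain[1]], chain)
  chain
}

simulate_lineage <- function(cfg, fov, duration) {
  dt <- cfg$frame_interval
  n_frames <- floor(duration / dt) + 1L
  t_frames <- (seq_len(n_frames) - 1L) * dt

  cells <- list(); rounds <- list(); events <- list()
  next_uid <- 1L

  ## founder at a uniformly random phase of its cycle
  Lb0 <- rtnorm(1, cfg$birth_length_mean, cfg$birth_length_sd,
                cfg$birth_length_mean - 2.5 * cfg$birth_length_sd,
                cfg$birth_length_mean + 2.5 * cfg$birth_length_sd)
  t0f <- rtnorm(1, cfg$t0_mean, cfg$t0_sd,
                cfg$t0_mean - 2.8 * cfg$t0_sd, cfg$t0_mean + 2.8 * cfg$t0_sd)
  Ldivf <- cfg$division_length_mean *
    exp(rtnorm(1, 0, cfg$division_length_cv,
               -2.5 * cfg$division_length_cv, 2.5 * cfg$division_length_cv))
  Ldivf <- max(Ldivf, Lb0 * 1.15)
  cyc0 <- t0f * log(Ldivf / Lb0)
  age0 <- stats::runif(1, 0, cyc0)
  if (stats::runif(1) < cfg$p_preinit) {
    init0 <- -age0 - stats::runif(1, 0, 35)
  } else {
    init0 <- -age0 + stats::runif(1, 5, 45)
  }
  queue <- list(list(tb = -age0, Lb = Lb0, parent = NA_integer_, side = NA,
                     key = c(0, 1), init_time = init0, init_in_parent = FALSE,
                     parent_split = NA_real_, t0 = t0f, Ldiv = Ldivf))

  while (length(queue)) {
    sp <- queue[[1]]; queue <- queue[-1]
    if (sp$tb > duration) next
    uid <- next_uid; next_uid <- next_uid + 1L
    t0c <- sp$t0 %||% rtnorm(1, cfg$t0_mean, cfg$t0_sd,
                             cfg$t0_mean - 2.8 * cfg$t0_sd,
                             cfg$t0_mean + 2.8 * cfg$t0_sd)
    Ldiv <- sp$Ldiv %||% max(cfg$division_length_mean *
      exp(rtnorm(1, 0, cfg$division_length_cv,
                 -2.5 * cfg$division_length_cv,
                 2.5 * cfg$division_length_cv)), sp$Lb * 1.15)
    td <- sp$tb + t0c * log(Ldiv / sp$Lb)
    div_silent <- stats::runif(1) < cfg$p_chain

    ## replication round terminating in this cell
    t_ri_L <- NA_real_; t_ri_R <- NA_real_; pre <- NA
    if (!is.na(sp$init_time)) {
      C <- rtnorm(1, cfg$replication_duration_mean,
                  cfg$replication_duration_sd, lo = 40)
      t_term <- min(sp$init_time + C, td - dt)
      t_term <- max(t_term, sp$init_time + dt)
      rounds[[uid]] <- data.frame(
        fov = fov, cell = uid, t_init = sp$init_time, t_term = t_term,
        init_in_parent = sp$init_in_parent, parent = sp$parent,
        side = ifelse(is.na(sp$side), "", sp$side),
        parent_split = sp$parent_split)
      if (cfg$reinit_enabled) {
        pre <- stats::runif(1) < cfg$p_preinit
        D <- rtnorm(1, cfg$d_period_mean, cfg$d_period_sd, lo = 10)
        if (pre) {
          ## re-initiation strictly between termination and division;
          ## termination precedes division by at least one frame, so there
          ## is always room and the Bernoulli is realized exactly
          t_ri <- t_term + D
          if (t_ri > td - 1) t_ri <- stats::runif(1, t_term + 1, td - 1)
          t_ri_L <- t_ri_R <- t_ri
        } else {
          base_ri <- max(td + dt / 2, t_term + D)
          t_ri_L <- base_ri + stats::runif(1, 0, 10)
          t_ri_R <- base_ri + stats::runif(1, 0, 10)
        }
        events[[uid]] <- data.frame(
          fov = fov, cell = uid, init_time = sp$init_time,
          term_time = t_term, div_time = td,
          reinit_time = min(t_ri_L, t_ri_R), preinit = pre)
      } else {
        events[[uid]] <- data.frame(
          fov = fov, cell = uid, init_time = sp$init_time,
          term_time = t_term, div_time = td,
          reinit_time = NA_real_, preinit = NA)
      }
    }

    cells[[uid]] <- data.frame(
      fov = fov, cell = uid, parent = sp$parent,
      side = ifelse(is.na(sp$side), "", sp$side),
      tb = sp$tb, td = td, Lb = sp$Lb, Ldiv = Ldiv, t0 = t0c,
      key = sp$key[1], div_silent = div_silent)

    if (td <= duration) {
      split <- rtnorm(1, 0.5, cfg$division_asym_sd, 0.475, 0.525)
      mid <- mean(sp$key)
      queue <- c(queue, list(
        list(tb = td, Lb = Ldiv * split, parent = uid, side = "L",
             key = c(sp$key[1], mid), init_time = t_ri_L,
             init_in_parent = isTRUE(pre), parent_split = split,
             t0 = NULL, Ldiv = NULL),
        list(tb = td, Lb = Ldiv * (1 - split), parent = uid, side = "R",
             key = c(mid, sp$key[2]), init_time = t_ri_R,
             init_in_parent = isTRUE(pre), parent_split = split,
             t0 = NULL, Ldiv = NULL)))
      cells[[uid]]$split <- split
    } else {
      cells[[uid]]$split <- NA_real_
    }
  }

  cells <- do.call(rbind, cells)
  rounds <- if (length(rounds)) do.call(rbind, rounds) else NULL
  events <- if (length(events)) do.call(rbind, events) else NULL
  parent_of <- cells$parent[order(cells$cell)]
  chains <- lapply(cells$cell, ancestor_chain, parent_of = parent_of)

  ## ---- per-frame cell geometry and mask groups ----
  cf <- vector("list", n_frames)
  group_registry <- new.env(parent = emptyenv())
  next_group_label <- max(cells$cell) + 1L
  for (f in seq_len(n_frames)) {
    t <- t_frames[f]
    act <- which(cells$tb <= t & t < cells$td)
    if (!length(act)) next
    act <- act[order(cells$key[act])]
    L <- cells$Lb[act] * exp((t - cells$tb[act]) / cells$t0[act])
    xr <- cumsum(L) - sum(L) / 2
    xl <- xr - L
    n <- length(act)
    ## adjacent cells belong to one mask group iff the division at their
    ## deepest common ancestor was silent (chaining)
    joined <- rep(FALSE, max(n - 1, 0))
    if (n > 1 && cfg$p_chain > 0) {
      for (i in seq_len(n - 1)) {
        c1 <- chains[[act[i]]]; c2 <- chains[[act[i + 1]]]
        k <- max(which(c1[seq_len(min(length(c1), length(c2)))] ==
                         c2[seq_len(min(length(c1), length(c2)))]))
        joined[i] <- cells$div_silent[c1[k]]
      }
    }
    gid <- cumsum(c(TRUE, !joined))
    glab <- integer(n); gcx <- numeric(n); glen <- numeric(n)
    for (g in unique(gid)) {
      mem <- which(gid == g)
      if (length(mem) == 1L) {
        lab <- cells$cell[act[mem]]
      } else {
        gkey <- paste(cells$cell[act[mem]], collapse = "|")
        if (is.null(group_registry[[gkey]])) {
          group_registry[[gkey]] <- next_group_label
          next_group_label <- next_group_label + 1L
        }
        lab <- group_registry[[gkey]]
      }
      glab[mem] <- lab
      gcx[mem] <- (xl[mem[1]] + xr[mem[length(mem)]]) / 2
      glen[mem] <- xr[mem[length(mem)]] - xl[mem[1]]
    }
    cf[[f]] <- data.frame(
      fov = fov, frame = f - 1L, cell = cells$cell[act], t = t,
      length_um = L, cx_um = (xl + xr) / 2, cy_um = 0, theta = 0,
      x_l_um = xl, group = glab, gcx_um = gcx, glength_um = glen)
  }
  cell_frames <- do.call(rbind, cf)

  ## ---- emitter trajectories per round ----
  em <- list()
  if (!is.null(rounds)) {
    for (i in seq_len(nrow(rounds))) {
      r <- rounds[i, ]
      ff <- which(t_frames >= r$t_init & t_frames < r$t_term)
      if (!length(ff)) next
      tb_c <- cells$tb[cells$cell == r$cell]
      o <- stats::rnorm(1, 0, cfg$confinement_sd)
      yo <- stats::rnorm(1, 0, 0.04)
      resolved <- stats::runif(1) < cfg$p_resolved
      sep <- NA_real_  # drawn lazily once the host length is known
      prev_in_parent <- NA
      rows <- vector("list", length(ff))
      for (j in seq_along(ff)) {
        f <- ff[j]; t <- t_frames[f]
        in_parent <- r$init_in_parent && t < tb_c
        host <- if (in_parent) r$parent else r$cell
        home <- if (in_parent) {
          if (r$side == "L") 0.5 - cfg$quarter_offset else 0.5 + cfg$quarter_offset
        } else 0.5
        if (!is.na(prev_in_parent) && prev_in_parent && !in_parent) {
          ## division: map the factory into the daughter's frame
          pos_p <- home_prev + o
          iv <- if (r$side == "L") c(0, r$parent_split) else c(r$parent_split, 1)
          o <- (pos_p - iv[1]) / (iv[2] - iv[1]) - 0.5
          o <- pmin(pmax(o, -0.12), 0.12)
          sep <- NA_real_  # separation rescales with the new host
        }
        hrow <- cell_frames[cell_frames$frame == f - 1L &
                              cell_frames$cell == host, , drop = FALSE]
        if (nrow(hrow) == 1L) {
          if (resolved && is.na(sep)) sep <- draw_sep(cfg, hrow$length_um)
          xs <- if (resolved) home + o + c(-sep, sep) / 2 else home + o
          xs <- pmin(pmax(xs, 0.04), 0.96)
          st <- if (resolved) "resolved" else "colocalized"
          x_abs <- hrow$x_l_um + xs * hrow$length_um
          rows[[j]] <- data.frame(
            fov = fov, frame = f - 1L, cell = host, pair = r$cell,
            state = st, x_rel = xs, y_off_um = yo,
            x_um = x_abs, y_um = yo, group = hrow$group,
            group_x_rel = (x_abs - (hrow$gcx_um - hrow$glength_um / 2)) /
              hrow$glength_um)
        }
        home_prev <- home; prev_in_parent <- in_parent
        ## evolve state to the next frame
        o <- cfg$ar_rho * o +
          stats::rnorm(1, 0, cfg$confinement_sd * sqrt(1 - cfg$ar_rho^2))
        yo <- cfg$ar_rho * yo + stats::rnorm(1, 0, 0.04 * sqrt(1 - cfg$ar_rho^2))
        if (resolved) {
          resolved <- stats::runif(1) < cfg$res_persist
          if (!resolved) sep <- NA_real_
        } else {
          q01 <- cfg$p_resolved * (1 - cfg$res_persist) / (1 - cfg$p_resolved)
          resolved <- stats::runif(1) < q01
          sep <- NA_real_  # drawn at the next emission frame
        }
      }
      em[[length(em) + 1L]] <- do.call(rbind, rows)
    }
  }
  emitters <- if (length(em)) do.call(rbind, em) else NULL

  list(cells = cells, rounds = rounds, events = events,
       cell_frames = cell_frames, emitters = emitters, n_frames = n_frames)
}

## snapshot population: independent cells at random phases, packed into
## shared frames with random in-plane orientation
simulate_snapshot <- function(cfg, n_cells) {
  shape <- cfg$image_shape %||% c(512L, 512L)
  px_um <- cfg$pixel_size / 1000
  margin_px <- 45
  spacing_px <- ceiling(4.6 / px_um / 1.15)
  per_row <- max(1L, floor((shape[1] - 2 * margin_px) / spacing_px) + 1L)
  per_col <- max(1L, floor((shape[2] - 2 * margin_px) / spacing_px) + 1L)
  per_frame <- per_row * per_col

  cells <- list(); events <- list(); cf <- list(); em <- list()
  for (i in seq_len(n_cells)) {
    Lb <- rtnorm(1, cfg$birth_length_mean, cfg$birth_length_sd,
                 cfg$birth_length_mean - 2.5 * cfg$birth_length_sd,
                 cfg$birth_length_mean + 2.5 * cfg$birth_length_sd)
    t0c <- rtnorm(1, cfg$t0_mean, cfg$t0_sd,
                  cfg$t0_mean - 2.8 * cfg$t0_sd, cfg$t0_mean + 2.8 * cfg$t0_sd)
    Ldiv <- max(cfg$division_length_mean *
      exp(rtnorm(1, 0, cfg$division_length_cv,
                 -2.5 * cfg$division_length_cv,
                 2.5 * cfg$division_length_cv)), Lb * 1.15)
    cyc <- t0c * log(Ldiv / Lb)
    ## age density of an exponentially growing population
    a <- -cyc * log2(1 - stats::runif(1) / 2)
    ## replication schedule for this cycle
    if (stats::runif(1) < cfg$p_preinit) {
      t_init <- -stats::runif(1, 0, 35)
    } else {
      t_init <- stats::runif(1, 5, 45)
    }
    C <- rtnorm(1, cfg$replication_duration_mean,
                cfg$replication_duration_sd, lo = 40)
    t_term <- max(min(t_init + C, cyc - 5), t_init + 5)
    pre <- cfg$reinit_enabled && stats::runif(1) < cfg$p_preinit
    D <- rtnorm(1, cfg$d_period_mean, cfg$d_period_sd, lo = 10)
    t_ri <- if (!cfg$reinit_enabled) NA_real_ else if (pre) {
      ri <- t_term + D
      if (ri > cyc - 1) ri <- stats::runif(1, t_term + 1, cyc - 1)
      ri
    } else cyc + D

    frame <- (i - 1L) %/% per_frame
    slot <- (i - 1L) %% per_frame
    gx <- slot %% per_row; gy <- slot %/% per_row
    cx <- (margin_px + gx * spacing_px + stats::runif(1, -6, 6) -
             (shape[1] + 1) / 2) * px_um
    cy <- (margin_px + gy * spacing_px + stats::runif(1, -6, 6) -
             (shape[2] + 1) / 2) * px_um
    theta <- stats::runif(1, 0, pi)
    L <- Lb * exp(a / t0c)

    cells[[i]] <- data.frame(fov = 1L, cell = i, parent = NA_integer_,
                             side = "", tb = -a, td = cyc - a, Lb = Lb,
                             Ldiv = Ldiv, t0 = t0c, key = i,
                             div_silent = FALSE, split = NA_real_)
    events[[i]] <- data.frame(fov = 1L, cell = i, init_time = t_init - a,
                              term_time = t_term - a, div_time = cyc - a,
                              reinit_time = t_ri - a, preinit = pre)
    cf[[i]] <- data.frame(fov = 1L, frame = frame, cell = i, t = 0,
                          length_um = L, cx_um = cx, cy_um = cy,
                          theta = theta, x_l_um = NA_real_, group = i,
                          gcx_um = cx, glength_um = L)

    mk_pair <- function(home, pid) {
      o <- stats::rnorm(1, 0, cfg$confinement_sd)
      yo <- stats::rnorm(1, 0, 0.04)
      resolved <- stats::runif(1) < cfg$p_resolved
      xs <- if (resolved) {
        sep <- draw_sep(cfg, L); home + o + c(-sep, sep) / 2
      } else home + o
      xs <- pmin(pmax(xs, 0.04), 0.96)
      ux <- cos(theta); uy <- sin(theta)
      data.frame(fov = 1L, frame = frame, cell = i, pair = pid,
                 state = if (resolved) "resolved" else "colocalized",
                 x_rel = xs, y_off_um = yo,
                 x_um = cx + (xs - 0.5) * L * ux - yo * uy,
                 y_um = cy + (xs - 0.5) * L * uy + yo * ux,
                 group = i, group_x_rel = xs)
    }
    if (a >= t_init && a < t_term) {
      em[[length(em) + 1L]] <- mk_pair(0.5, i * 10L)
    } else if (!is.na(t_ri) && pre && a >= t_ri) {
      em[[length(em) + 1L]] <- rbind(
        mk_pair(0.5 - cfg$quarter_offset, i * 10L + 1L),
        mk_pair(0.5 + cfg$quarter_offset, i * 10L + 2L))
    }
  }
  list(cells = do.call(rbind, cells), rounds = NULL,
       events = do.call(rbind, events),
       cell_frames = do.call(rbind, cf),
       emitters = if (length(em)) do.call(rbind, em) else NULL,
       n_frames = (n_cells - 1L) %/% per_frame + 1L)
}

#' Simulate a population of replicating cells
#'
#' Runs the factory-model cell-cycle simulator and returns the ground truth:
#' cell records with lineage, per-cycle replication events
#' (initiation/termination/re-initiation vs division), per-frame cell
#' geometry, and per-frame emitter positions with their
#' co-localized/resolved state.  Deterministic given `config$seed`.
#'
#' @param config a [sim_config()] / [sim_preset()] configuration.
#' @param n_cells number of founder lineages (time-lapse) or of independent
#'   cells (snapshot mode).
#' @param duration simulated time in minutes (ignored in snapshot mode).
#' @return an object of class `replisim_truth`: a list with data.frames
#'   `cells`, `events`, `cell_frames`, `emitters`, plus `n_frames` and the
#'   `config` used.
#' @export
simulate_population <- function(config, n_cells, duration = 300) {
  validate_sim_config(config)
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (!config$snapshot && duration < config$frame_interval)
    stop("duration must be >= frame_interval")
  truth <- withr::with_seed(config$seed, {
    if (config$snapshot) {
      simulate_snapshot(config, n_cells)
    } else {
      fovs <- lapply(seq_len(n_cells), function(fov)
        simulate_lineage(config, fov, duration))
      list(cells = do.call(rbind, lapply(fovs, `[[`, "cells")),
           rounds = do.call(rbind, lapply(fovs, `[[`, "rounds")),
           events = do.call(rbind, lapply(fovs, `[[`, "events")),
           cell_frames = do.call(rbind, lapply(fovs, `[[`, "cell_frames")),
           emitters = do.call(rbind, lapply(fovs, `[[`, "emitters")),
           n_frames = fovs[[1]]$n_frames)
    }
  })
  truth$config <- config
  truth$duration <- if (config$snapshot) config$frame_interval else duration
  class(truth) <- "replisim_truth"
  truth
}

#' @export
print.replisim_truth <- function(x, ...) {
  cat("replisim_truth:", nrow(x$cells), "cells,",
      length(unique(x$cell_frames$fov)), "fields,", x$n_frames, "frames,",
      if (is.null(x$emitters)) 0L else nrow(x$emitters), "emitter records\n")
  invisible(x)
}

#' Fraction of replication cycles with pre-division re-initiation
#'
#' Counts, over completed cycles in the exported event table, how often the
#' next round's initiation precedes the enclosing cell's division.
#'
#' @param truth a `replisim_truth`.
#' @return fraction in `[0, 1]`.
#' @export
preinit_fraction <- function(truth) {
  ev <- truth$events
  ev <- ev[!is.na(ev$reinit_time) & !is.na(ev$div_time), , drop = FALSE]
  ev <- ev[ev$div_time <= truth$duration &
             pmin(ev$reinit_time, ev$div_time) <= truth$duration, , drop = FALSE]
  if (!nrow(ev)) stop("no completed replication cycles in the event table")
  mean(ev$reinit_time < ev$div_time)
}
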