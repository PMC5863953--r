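S1_COLUMNS <- c(
  "solo_error_1", "solo_error_2", "conn_error_1", "conn_error_2",
  "solo_effort_1", "solo_effort_2", "conn_effort_1", "conn_effort_2",
  "solo_cocon_1", "solo_cocon_2", "conn_cocon_1", "conn_cocon_2",
  "solo_recip_1", "solo_recip_2", "conn_recip_1", "conn_recip_2",
  "stiffness_nm_deg", "dyad", "order"
)

#' Generate a synthetic dyad dataset with the experiment's structure
#'
#' Simulates `n_dyads` pairs through the full 45-trial protocol (3 stiffness
#' blocks of 15 trials, medium first, hard/soft order randomized per dyad,
#' each trial connected with probability 1/2) under one interaction
#' strategy, pairs each solo trial with its preceding connected trial, and
#' returns the pair table in the 19-column trial-data layout. Per-subject
#' visual noise (the skill knob) is drawn uniformly over `skill_range`.
#'
#' @param n_dyads Number of simulated pairs (>= 2; default 14).
#' @param strategy `"neuromechanical"`, `"goal_integration"` or
#'   `"follow_leader"`.
#' @param seed Master integer seed.
#' @param skill_range Range (degrees) of the per-subject visual noise SD
#'   (default 1-5, spanning solo errors of roughly 1.8-5.4 degrees).
#' @param noise_model A [haptic_noise_model()]; when `NULL` and the strategy
#'   is neuromechanical, the simulated haptic-tracking calibration is run
#'   (seeded from `seed`). Goal integration uses `sigma_s2 = 0`.
#' @param q,sigma_mu2 Controller/internal-model parameters for every agent.
#' @param duration,dt Trial length (s) and step (s).
#' @param n_per_block Trials per stiffness block (default 15).
#' @param cocontraction Constant filling the co-contraction columns (the
#'   headline analysis never uses them; the format requires them).
#' @return List with `records` (class `dyad_records`: one row per pair in
#'   the 19-column layout, stiffness in Nm/deg), `paired` (the long
#'   [pair_trials()] table with an `order` column), and `noise_model`.
#' @export
generate_dyad_dataset <- function(n_dyads = 14,
                                  strategy = c("neuromechanical",
                                               "goal_integration",
                                               "follow_leader"),
                                  seed = 1,
                                  skill_range = c(1, 5),
                                  noise_model = NULL,
                                  q = 1, sigma_mu2 = 2e-2,
                                  duration = 40, dt = 0.005,
                                  n_per_block = 15,
                                  cocontraction = 0.1) {
  strategy <- match.arg(strategy)
  if (n_dyads < 2) stop("`n_dyads` must be >= 2", call. = FALSE)
  if (is.null(noise_model)) {
    noise_model <- if (strategy == "neuromechanical") {
      calibrate_haptic_noise(
        agent_spec(sigma_v_deg = mean(skill_range), sigma_mu2 = sigma_mu2,
                   q = q, dt = dt, sigma_f = 0.1),
        seed = seed, duration = duration, dt = dt)
    } else {
      haptic_noise_model(c(hard = 0, medium = 0, soft = 0))
    }
  }
  paired_all <- list()
  for (d in seq_len(n_dyads)) {
    dseed <- seed * 1000L + d
    set.seed(dseed)
    sv <- stats::runif(2, skill_range[1], skill_range[2])
    ag <- lapply(sv, function(s) {
      agent_spec(sigma_v_deg = s, sigma_mu2 = sigma_mu2, q = q, dt = dt)
    })
    sched <- build_schedule(seed = dseed, n_per_block = n_per_block,
                            trial_duration = duration)
    met <- list()
    for (i in seq_len(nrow(sched))) {
      tseed <- dseed * 100L + i
      traj <- generate_target(duration, dt, seed = tseed)
      if (sched$connected[i]) {
        cp <- coupling_spec(sched$stiffness[i], inertia = ag[[1]]$inertia)
        s2 <- noise_model$sigma_s2[[sched$level[i]]]
        tr <- run_dyad(ag[[1]], ag[[2]], cp, traj, strategy = strategy,
                       seed = tseed, sigma_s2_deg2 = s2)
        err <- c(tr$agent1$rms_error_deg, tr$agent2$rms_error_deg)
        eff <- c(tr$agent1$effort_nm, tr$agent2$effort_nm)
      } else {
        r1 <- run_solo(ag[[1]], traj, seed = tseed * 2L)
        r2 <- run_solo(ag[[2]], traj, seed = tseed * 2L + 1L)
        err <- c(r1$rms_error_deg, r2$rms_error_deg)
        eff <- c(r1$effort_nm, r2$effort_nm)
      }
      if (any(!is.finite(err))) {
        stop("simulation diverged at dyad ", d, ", trial ", i, call. = FALSE)
      }
      met[[i]] <- data.frame(trial = i, subject = 1:2, error_deg = err,
                             effort = eff)
    }
    paired <- pair_trials(do.call(rbind, met), sched, dyad = d)
    paired$order <- attr(sched, "order")
    paired_all[[d]] <- paired
  }
  paired <- do.call(rbind, paired_all)
  class(paired) <- c("paired_outcomes", "data.frame")
  list(records = paired_to_records(paired, cocontraction = cocontraction),
       paired = paired, noise_model = noise_model, strategy = strategy)
}

#' Convert a long paired-outcome table to the 19-column record layout
#'
#' @param paired A [pair_trials()] table with both subjects per pair and an
#'   `order` column.
#' @param cocontraction Constant for the co-contraction columns.
#' @return `dyad_records` data.frame (stiffness in Nm/deg).
#' @export
paired_to_records <- function(paired, cocontraction = 0.1) {
  key <- interaction(paired$dyad, paired$solo_trial, paired$conn_trial,
                     drop = TRUE)
  rows <- lapply(split(paired, key), function(p) {
    p <- p[order(p$subject), ]
    if (nrow(p) != 2) return(NULL)
    data.frame(
      solo_error_1 = p$e[1], solo_error_2 = p$e[2],
      conn_error_1 = p$e_c[1], conn_error_2 = p$e_c[2],
      solo_effort_1 = p$alpha[1], solo_effort_2 = p$alpha[2],
      conn_effort_1 = p$alpha_c[1], conn_effort_2 = p$alpha_c[2],
      solo_cocon_1 = cocontraction, solo_cocon_2 = cocontraction,
      conn_cocon_1 = cocontraction, conn_cocon_2 = cocontraction,
      solo_recip_1 = p$alpha[1], solo_recip_2 = p$alpha[2],
      conn_recip_1 = p$alpha_c[1], conn_recip_2 = p$alpha_c[2],
      stiffness_nm_deg = nm_per_rad_to_nm_per_deg(p$stiffness[1]),
      dyad = p$dyad[1],
      order = if ("order" %in% names(p)) p$order[1] else NA_integer_
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  rec <- do.call(rbind, rows)
  rec <- rec[order(rec$dyad), ]
  rownames(rec) <- NULL
  class(rec) <- c("dyad_records", "data.frame")
  rec
}

#' Expand a 19-column record table into the long paired-outcome table
#'
#' Computes improvement, relative error and interaction effort per subject
#' from the stored errors and efforts; stiffness is converted to Nm/rad.
#'
#' @param records A `dyad_records` table (e.g. from [read_s1()]).
#' @param effort_definition Passed to [interaction_effort()].
#' @return A `paired_outcomes` data.frame.
#' @export
records_to_paired <- function(records,
                              effort_definition = "connected_over_solo") {
  rows <- list()
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    k_rad <- nm_per_deg_to_nm_per_rad(r$stiffness_nm_deg)
    lev <- names(stiffness_levels())[
      which.min(abs(stiffness_levels() - k_rad))]
    for (subj in 1:2) {
      e <- r[[paste0("solo_error_", subj)]]
      e_p <- r[[paste0("solo_error_", 3 - subj)]]
      e_c <- r[[paste0("conn_error_", subj)]]
      a <- r[[paste0("solo_effort_", subj)]]
      a_c <- r[[paste0("conn_effort_", subj)]]
      rows[[length(rows) + 1L]] <- data.frame(
        dyad = r$dyad, subject = subj, block = NA_integer_, level = lev,
        stiffness = k_rad, kappa = log10(k_rad),
        solo_trial = i, conn_trial = i,
        e = e, e_c = e_c, e_p = e_p, alpha = a, alpha_c = a_c,
        delta_c = 1 - e_c / e, delta_p = 1 - e_p / e,
        order = r$order, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$effort <- interaction_effort(out$alpha, out$alpha_c,
                                   definition = effort_definition)
  class(out) <- c("paired_outcomes", "data.frame")
  out
}

#' Read a 19-column dyad trial-pair text file
#'
#' Whitespace- or tab-delimited numeric text, one row per connected/solo
#' trial pair, columns in the standard order (errors in degrees, efforts,
#' co-contraction and reciprocal activation, stiffness in Nm/deg, dyad id,
#' block order). The stiffness column is validated against the three
#' experimental levels after conversion to Nm/rad.
#'
#' @param path File path.
#' @return A `dyad_records` data.frame.
#' @export
read_s1 <- function(path) {
  raw <- utils::read.table(path, header = FALSE, fill = TRUE)
  raw <- check_s1_matrix(as.matrix(raw), path)
  rec <- as.data.frame(raw)
  names(rec) <- S1_COLUMNS
  class(rec) <- c("dyad_records", "data.frame")
  rec
}

check_s1_matrix <- function(m, path) {
  if (ncol(m) != 19) {
    stop("expected 19 columns in ", path, ", found ", ncol(m), call. = FALSE)
  }
  bad <- which(!stats::complete.cases(m))
  if (length(bad)) {
    stop("non-numeric or missing cells in ", path, " at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  err <- m[, 1:4]
  if (any(err <= 0)) {
    stop("non-positive tracking errors in ", path, " at row(s) ",
         paste(utils::head(which(rowSums(err <= 0) > 0), 5), collapse = ", "),
         call. = FALSE)
  }
  k_rad <- nm_per_deg_to_nm_per_rad(m[, 17])
  lv <- stiffness_levels()
  off <- vapply(k_rad, function(k) min(abs(k - lv) / lv), numeric(1))
  if (any(off > 0.05)) {
    stop("stiffness values in ", path, " do not match the hard/medium/soft ",
         "levels after Nm/deg -> Nm/rad conversion (row ",
         which.max(off > 0.05), ")", call. = FALSE)
  }
  m
}

#' Write a record table in the 19-column text dialect
#'
#' Tab-delimited, no header; lossless round trip with [read_s1()].
#'
#' @param records A `dyad_records` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_s1 <- function(records, path) {
  stopifnot(ncol(records) == 19)
  utils::write.table(as.data.frame(records), path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a haptic-tracking text file
#'
#' 30 rows x one column per subject: rows 1-15 are per-trial tracking errors
#' (degrees), rows 16-30 the connection stiffness of the matching trial
#' (Nm/deg, constant in blocks of 5: five trials per level).
#'
#' @param path File path.
#' @return A long data.frame `subject`, `trial`, `stiffness` (Nm/rad),
#'   `error_deg`, of class `haptic_tracking_record`.
#' @export
read_s2 <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (nrow(m) != 30) {
    stop("expected 30 rows in ", path, ", found ", nrow(m), call. = FALSE)
  }
  if (any(!is.finite(m))) stop("non-numeric cells in ", path, call. = FALSE)
  n_sub <- ncol(m)
  err <- m[1:15, , drop = FALSE]
  stf <- m[16:30, , drop = FALSE]
  for (b in seq(1, 15, by = 5)) {
    blk <- stf[b:(b + 4), , drop = FALSE]
    if (any(abs(sweep(blk, 2, blk[1, ])) > 1e-9)) {
      stop("stiffness rows not constant in blocks of 5 in ", path,
           " (rows ", 15 + b, "-", 15 + b + 4, ")", call. = FALSE)
    }
  }
  out <- data.frame(
    subject = rep(seq_len(n_sub), each = 15),
    trial = rep(1:15, n_sub),
    stiffness = nm_per_deg_to_nm_per_rad(as.vector(stf)),
    error_deg = as.vector(err)
  )
  class(out) <- c("haptic_tracking_record", "data.frame")
  out
}

#' Write a haptic-tracking table in the 30-row text dialect
#'
#' @param record A `haptic_tracking_record` long table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_s2 <- function(record, path) {
  n_sub <- length(unique(record$subject))
  err <- matrix(record$error_deg, nrow = 15)
  stf <- matrix(nm_per_rad_to_nm_per_deg(record$stiffness), nrow = 15)
  utils::write.table(rbind(err, stf), path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Simulate paired outcomes from the regression model directly
#'
#' Draws a paired-outcome table from the quadratic improvement model and the
#' linear effort model with known coefficients, dyad random intercepts and
#' residual noise — the generative counterpart of the statistical pipeline,
#' used for coefficient recovery, type-I calibration and power checks
#' without running any physical simulation.
#'
#' @param n_dyads Number of dyads.
#' @param n_pairs_per_level Pairs per dyad per stiffness level.
#' @param beta_improvement Named coefficients `intercept, dp, kappa, dp2,
#'   dp_kappa, dp2_kappa`.
#' @param beta_effort Named coefficients `intercept, dp, kappa, dp_kappa`.
#' @param sd_dyad Random-intercept SD (shared by both responses).
#' @param sd_res Residual SD.
#' @param sd_dp Spread of the per-dyad skill asymmetry driving `delta_p`.
#' @param seed Integer seed.
#' @return A `paired_outcomes`-style data.frame with an `order` column.
#' @export
simulate_paired_outcomes <- function(n_dyads = 14, n_pairs_per_level = 7,
                                     beta_improvement = c(intercept = 0.1,
                                                          dp = 0.3,
                                                          kappa = 0.05,
                                                          dp2 = -0.1,
                                                          dp_kappa = 0.15,
                                                          dp2_kappa = 0.05),
                                     beta_effort = c(intercept = 0.05,
                                                     dp = -0.15,
                                                     kappa = 0.08,
                                                     dp_kappa = -0.1),
                                     sd_dyad = 0.05, sd_res = 0.15,
                                     sd_dp = 0.25, seed = 1) {
  set.seed(seed)
  ks <- stiffness_levels()
  rows <- list()
  for (d in seq_len(n_dyads)) {
    b_d <- stats::rnorm(1, 0, sd_dyad)
    asym <- stats::rnorm(1, 0, sd_dp)
    ord <- stats::rbinom(1, 1, 0.5)
    for (lev in names(ks)) {
      kappa <- log10(ks[[lev]])
      for (p in seq_len(n_pairs_per_level)) {
        for (subj in 1:2) {
          dp <- (if (subj == 1) asym else -asym) +
            stats::rnorm(1, 0, sd_dp / 4)
          bi <- beta_improvement
          dc <- bi[["intercept"]] + bi[["dp"]] * dp + bi[["kappa"]] * kappa +
            bi[["dp2"]] * dp^2 + bi[["dp_kappa"]] * dp * kappa +
            bi[["dp2_kappa"]] * dp^2 * kappa + b_d +
            stats::rnorm(1, 0, sd_res)
          be <- beta_effort
          ef <- be[["intercept"]] + be[["dp"]] * dp + be[["kappa"]] * kappa +
            be[["dp_kappa"]] * dp * kappa + b_d + stats::rnorm(1, 0, sd_res)
          e <- stats::runif(1, 1, 6)
          rows[[length(rows) + 1L]] <- data.frame(
            dyad = d, subject = subj, block = match(lev, names(ks)),
            level = lev, stiffness = ks[[lev]], kappa = kappa,
            solo_trial = p, conn_trial = p,
            e = e, e_c = e * (1 - dc), e_p = e * (1 - dp),
            alpha = 1, alpha_c = 1 + ef,
            delta_c = dc, delta_p = dp, effort = ef, order = ord,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("paired_outcomes", "data.frame")
  out
}
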