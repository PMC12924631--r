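# Herd simulator: stocks pigs across barns, advances them daily through
# growth -> energy -> requirements, removes pigs at target weight, and runs
# replications. The engine is vectorized over agents (replication x pig),
# which is observationally equivalent to agent-wise scheduling because each
# pig consumes its own pre-derived RNG substream: results are independent
# of update order and of which other pigs share the run.

# Deterministic per-pig substream seed. Kept below 2^31; the additive mixing
# guarantees distinct seeds for all (replication, pig) pairs in realistic
# herd sizes (pig ids < 126k per replication).
.substream_seed <- function(seed, replication, pig_id) {
  as.integer((abs(as.numeric(seed)) + 1000003 * as.numeric(replication) +
                7919 * as.numeric(pig_id)) %% 2147483647)
}

.make_agents <- function(config, n_replications) {
  n_per <- config$n_pigs_per_sex
  sexes <- config$sexes
  pig_id <- seq_len(n_per * length(sexes))
  sex <- rep(sexes, each = n_per)
  barn <- ((pig_id - 1L) %% config$n_barns) + 1L
  data.frame(
    replication = rep(seq_len(n_replications), each = length(pig_id)),
    pig_id = rep(pig_id, n_replications),
    sex = rep(sex, n_replications),
    barn = rep(barn, n_replications),
    stringsAsFactors = FALSE
  )
}

.sex_params_from_config <- function(config) {
  out <- lapply(config$sexes, function(s) {
    fi_override <- if (s == "boar") config$boar_fi_coeffs else NULL
    sex_params(s, bwg_coeffs = config$bwg_coeffs, fi_coeffs = fi_override)
  })
  names(out) <- config$sexes
  out
}

.record_vars <- c("bw", "bwg", "pd", "ld", "mei", "fi", "m_me",
                  "bp", "bl", "ebw", "pbt", "sid_lysine", "sttd_p",
                  "total_ca", "bw_ebw_drift")

#' Create a simulation in its stocked (day-0) state
#'
#' Stocks the agents of all replications, draws their initial body weights
#' from `Normal(bw_initial_mean, bw_initial_sd)` (deviates clamped at
#' +/- 4 sd), initializes body composition so the empty-body-weight
#' identity holds exactly, derives each pig's private RNG substream from
#' `(seed, replication, pig_id)`, and records the day-0 snapshot.
#'
#' @param config A [herd_config()].
#' @param n_replications Number of replications to run jointly (defaults to
#'   `config$n_replications`).
#' @param agents Optional agent table override (columns `replication`,
#'   `pig_id`, `sex`, `barn`); intended for testing scheduling-order
#'   independence.
#' @return An environment of class `sns_simulation`; advance it with
#'   [step_day()] or run it to completion with [run_replications()].
#' @export
new_simulation <- function(config, n_replications = config$n_replications,
                           agents = NULL) {
  stopifnot(inherits(config, "herd_config"), n_replications >= 1)
  if (is.null(agents)) agents <- .make_agents(config, n_replications)
  n <- nrow(agents)
  params <- .sex_params_from_config(config)
  nd1 <- config$run_days + 1L

  ss <- .substream_seed(config$seed, agents$replication, agents$pig_id)
  z <- vapply(seq_len(n), function(i) {
    set.seed(ss[i])
    stats::rnorm(nd1)
  }, numeric(nd1))
  dim(z) <- c(nd1, n)

  z0 <- pmin(pmax(z[1L, ], -4), 4)
  bw0 <- config$bw_initial_mean + config$bw_initial_sd * z0
  if (any(bw0 <= 0) || any(bw0 <= gut_fill(pmax(bw0, 1e-9))))
    stop("infeasible initial body weight (<= gut fill); check ",
         "bw_initial_mean / bw_initial_sd")

  sim <- new.env(parent = emptyenv())
  sim$config <- config
  sim$params <- params
  sim$agents <- agents
  sim$n <- n
  sim$idx_by_sex <- split(seq_len(n), agents$sex)[config$sexes]
  sim$z <- z
  sim$day <- 0L
  sim$alive <- rep(TRUE, n)
  sim$removal_day <- rep(NA_integer_, n)
  sim$bw <- bw0
  sim$bw0 <- bw0

  pd_max_by_agent <- vapply(params, `[[`, numeric(1), "pd_max")[agents$sex]
  sim$pd_max <- as.numeric(pd_max_by_agent)
  comp <- initialize_composition(bw0, sim$pd_max,
                                 config$lipid_protein_ratio)
  sim$bp <- comp$bp; sim$bl <- comp$bl
  sim$bwt <- comp$bwt; sim$ba <- comp$ba; sim$ebw <- comp$ebw
  sim$gutf <- comp$gutf

  sim$rec <- vector("list", nd1)
  .record_day(sim, seq_len(n), day = 0L, bwg = rep(0, n))
  newly <- sim$bw >= config$bw_final
  if (any(newly)) {
    sim$removal_day[newly] <- 0L
    sim$alive[newly] <- FALSE
  }
  class(sim) <- "sns_simulation"
  sim
}

# Evaluate the rate chain at the current state and store row `day` for
# agents `ia`. For day 0 this is a stocking snapshot (no state advance).
.record_day <- function(sim, ia, day, bwg) {
  cfg <- sim$config
  bw <- sim$bw[ia]
  sex <- sim$agents$sex[ia]
  n_ia <- length(ia)
  pd <- mei <- fi <- numeric(n_ia)
  for (s in cfg$sexes) {
    m <- sex == s
    if (!any(m)) next
    p <- sim$params[[s]]
    pd[m] <- protein_deposition(bw[m], p)
    mei[m] <- energy_intake(bw[m], p)
    fi[m] <- feed_intake(bw[m], p, cfg$me_content, cfg$feed_wastage)
  }
  maint <- maintenance_energy(bw, cfg$temperature, cfg$me_adj)
  # intake ceiling: cap FI, rescale MEI to the energy actually consumed
  cap <- max_feed_intake(bw, cfg$temperature) / 1000
  over <- fi > cap
  if (any(over)) {
    fi[over] <- cap[over]
    mei[over] <- fi[over] * cfg$me_content * (1 - cfg$feed_wastage)
  }
  ld <- lipid_deposition(mei, maint$m_me, pd)

  bp_old <- sim$bp[ia]
  if (day > 0L) {
    comp <- update_composition(
      list(bp = bp_old, bl = sim$bl[ia], gutf = sim$gutf[ia]),
      pd, ld, sim$pd_max[ia])
    sim$bp[ia] <- comp$bp; sim$bl[ia] <- comp$bl
    sim$bwt[ia] <- comp$bwt; sim$ba[ia] <- comp$ba; sim$ebw[ia] <- comp$ebw
  }
  bp <- sim$bp[ia]; bl <- sim$bl[ia]; ebw <- sim$ebw[ia]

  gutf <- if (cfg$gut_fill_current_bw) gut_fill(bw) else sim$gutf[ia]
  fdmi_kg <- feed_dry_matter_intake(fi, cfg$fdm)
  git <- git_lysine_loss(fdmi_kg * 1000)
  integ <- integument_lysine_loss(bw)
  lys <- sid_lysine(git, integ, pd, bw, sim$pd_max[ia])
  pret <- max_p_retention(bp_old, pd)
  sttd <- sttd_phosphorus(pret, fdmi_kg, bw, multiply = cfg$sttd_p_multiply)

  sim$rec[[day + 1L]] <- list(
    ia = ia, day = day,
    bw = bw, bwg = bwg, pd = pd, ld = ld, mei = mei, fi = fi,
    m_me = maint$m_me, bp = bp, bl = bl, ebw = ebw,
    pbt = backfat_thickness(bp, bl),
    sid_lysine = lys$total, sttd_p = sttd, total_ca = total_calcium(sttd),
    bw_ebw_drift = bw - (ebw + gutf))
  invisible(sim)
}

#' Advance a simulation by one day
#'
#' For every live pig, in order: stochastic gain -> weight update ->
#' protein deposition -> energy budget (with the thermal environment) ->
#' feed intake (capped at the intake ceiling, with MEI rescaled when the
#' cap binds) -> lipid deposition -> composition update -> requirements ->
#' record. Pigs at or above the target weight are then marked removed (the
#' market-day record exists; removed pigs receive no further updates).
#'
#' @param sim An `sns_simulation` from [new_simulation()].
#' @return The simulation, invisibly (mutated in place).
#' @export
step_day <- function(sim) {
  stopifnot(inherits(sim, "sns_simulation"))
  cfg <- sim$config
  if (sim$day >= cfg$run_days)
    stop("run is finished (day ", sim$day, " of ", cfg$run_days, ")")
  d <- sim$day + 1L
  ia <- which(sim$alive)
  if (length(ia)) {
    mu <- bwg_deterministic(sim$bw[ia], cfg$bwg_coeffs)
    g <- if (cfg$noise_cv == 0) mu else
      .apply_gain_noise(mu, cfg$noise_cv, sim$z[d + 1L, ia])
    sim$bw[ia] <- update_bw(sim$bw[ia], g)
    .record_day(sim, ia, day = d, bwg = g)
    newly <- ia[sim$bw[ia] >= cfg$bw_final]
    if (length(newly)) {
      sim$removal_day[newly] <- d
      sim$alive[newly] <- FALSE
    }
  }
  sim$day <- d
  invisible(sim)
}

#' @export
print.sns_simulation <- function(x, ...) {
  cat(sprintf("<sns_simulation> day %d/%d, %d/%d pigs on feed\n",
              x$day, x$config$run_days, sum(x$alive), x$n))
  invisible(x)
}

# Gather the per-day record chunks into one long data.table. Removed pigs
# stop being recorded, so trimming is automatic.
.collect_run <- function(sim) {
  recs <- sim$rec[!vapply(sim$rec, is.null, logical(1))]
  agent_idx <- unlist(lapply(recs, `[[`, "ia"), use.names = FALSE)
  days <- unlist(lapply(recs, function(r) rep(r$day, length(r$ia))),
                 use.names = FALSE)
  cols <- lapply(stats::setNames(nm = .record_vars), function(v)
    unlist(lapply(recs, `[[`, v), use.names = FALSE))
  ag <- sim$agents
  records <- data.table::as.data.table(c(
    list(replication = ag$replication[agent_idx],
         pig_id = ag$pig_id[agent_idx],
         sex = ag$sex[agent_idx],
         barn = ag$barn[agent_idx],
         day = days),
    cols))
  data.table::setorder(records, replication, pig_id, day)
  pigs <- data.table::data.table(
    replication = ag$replication, pig_id = ag$pig_id, sex = ag$sex,
    barn = ag$barn, bw_initial = sim$bw0, bw_final = sim$bw,
    removed = !is.na(sim$removal_day), removal_day = sim$removal_day,
    unfinished = is.na(sim$removal_day))
  data.table::setorder(pigs, replication, pig_id)
  structure(list(config = sim$config, records = records, pigs = pigs,
                 n_replications = max(ag$replication), days_run = sim$day),
            class = "sns_run")
}

#' Run replications of the herd simulation
#'
#' Runs `n_replications` independent replications to completion (the
#' 140-day horizon is a hard stop; a run also ends early once every pig has
#' reached the target weight). Replications are mutually independent:
#' every pig's randomness comes from a substream derived from
#' `(seed, replication, pig_id)`, so the output is invariant to execution
#' order and identical across repeated calls with the same config.
#'
#' @param config A [herd_config()].
#' @param n_replications Number of replications (defaults to
#'   `config$n_replications`).
#' @param agents Optional agent-table override, see [new_simulation()].
#' @return An object of class `sns_run`: a list with `config`, `records`
#'   (a `data.table`, one row per pig-day, ordered by replication, pig,
#'   day), `pigs` (stocking/removal bookkeeping) and `days_run`.
#' @examples
#' cfg <- herd_config(n_pigs_per_sex = 2, n_replications = 3, run_days = 40)
#' run <- run_replications(cfg)
#' head(run$records)
#' @export
run_replications <- function(config, n_replications = config$n_replications,
                             agents = NULL) {
  sim <- new_simulation(config, n_replications, agents = agents)
  while (sim$day < config$run_days && any(sim$alive)) step_day(sim)
  .collect_run(sim)
}

#' Run a single replication
#'
#' @param config A [herd_config()].
#' @param replication Replication index used to derive the RNG substreams
#'   (so replication `k` here is bit-identical to replication `k` of a
#'   joint [run_replications()] call).
#' @return An `sns_run` with one replication.
#' @export
run_simulation <- function(config, replication = 1L) {
  agents <- .make_agents(config, 1L)
  agents$replication <- as.integer(replication)
  run <- run_replications(config, n_replications = 1L, agents = agents)
  run
}

#' @export
print.sns_run <- function(x, ...) {
  cat(sprintf(
    "<sns_run> %d replication(s), %d pigs, %d record rows, %d day(s)\n",
    x$n_replications, nrow(x$pigs), nrow(x$records), x$days_run))
  if (any(x$pigs$unfinished))
    cat(sprintf("  %d pig(s) below target weight at the horizon\n",
                sum(x$pigs$unfinished)))
  invisible(x)
}

#' Stock the pigs of one replication
#'
#' Creates the day-0 herd: initial body weights drawn around the stocking
#' mean, round-robin barn assignment, and the solved initial body
#' composition.
#'
#' @param config A [herd_config()].
#' @param replication Replication index (selects the RNG substreams).
#' @return A data.frame with one row per pig: `pig_id`, `sex`, `barn`,
#'   `bw`, `bp`, `bl`, `bwt`, `ba`, `ebw`, `gutf`.
#' @export
stock_pigs <- function(config, replication = 1L) {
  agents <- .make_agents(config, 1L)
  agents$replication <- as.integer(replication)
  sim <- new_simulation(config, n_replications = 1L, agents = agents)
  data.frame(pig_id = agents$pig_id, sex = agents$sex, barn = agents$barn,
             bw = sim$bw, bp = sim$bp, bl = sim$bl, bwt = sim$bwt,
             ba = sim$ba, ebw = sim$ebw, gutf = sim$gutf,
             stringsAsFactors = FALSE)
}

#' Deterministic reference trajectory
#'
#' Runs a single pig of one sex with all noise disabled (zero gain CV,
#' zero initial-weight SD): the daily solution of the reference equations
#' themselves, used as the comparison series by the verification harness.
#'
#' @param config A [herd_config()] (its noise settings are overridden).
#' @param sex One of the configured sexes.
#' @return A `data.table` of the pig's records (one row per day).
#' @export
deterministic_trajectory <- function(config, sex = "gilt") {
  sex <- match.arg(sex, list_sexes())
  cfg_args <- unclass(config)
  cfg_args$sexes <- sex
  cfg_args$n_pigs_per_sex <- 1L
  cfg_args$n_replications <- 1L
  cfg_args$noise_cv <- 0
  cfg_args$bw_initial_sd <- 0
  det <- do.call(herd_config, cfg_args)
  run_replications(det)$records
}
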