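#' Cascade parameter constructors
#'
#' The care-cascade model combines three ingredients: where patients go
#' first (`sorting_distribution`), the probability that a visit at each tier
#' ends in correct treatment (`tier_quality`), and how unresolved patients
#' flow upward (`referral_rates`). Tiers are VC (village clinic), THC
#' (township health center), CH (county hospital).
#'
#' @param VC,THC,CH per-tier probabilities.
#' @return validated named numeric vectors of class `sp_sorting` /
#'   `sp_tier_quality`.
#' @name cascade_params
NULL

#' @rdname cascade_params
#' @export
sorting_distribution <- function(VC, THC, CH) {
  s <- c(VC = VC, THC = THC, CH = CH)
  if (any(s < 0 | s > 1)) stop_sp("sorting probabilities must lie in [0,1]")
  if (abs(sum(s) - 1) > 1e-9) stop_sp("sorting probabilities must sum to 1 (got %.12f)", sum(s))
  structure(s, class = "sp_sorting")
}

#' @rdname cascade_params
#' @export
tier_quality <- function(VC, THC, CH) {
  q <- c(VC = VC, THC = THC, CH = CH)
  if (any(q < 0 | q > 1)) stop_sp("treatment probabilities must lie in [0,1]")
  structure(q, class = "sp_tier_quality")
}

#' Referral rates of the cascade
#'
#' @param vc_thc share of VC starters referred to a THC.
#' @param vc_ch share of VC starters referred directly to a CH.
#' @param vc_thc_ch second-hop mass: share of VC starters who, having
#'   transferred to a THC, are subsequently referred to a CH (a subset of
#'   `vc_thc`).
#' @param thc_ch share of THC starters referred to a CH.
#' @param ch_out share of CH patients referred outward (exits the modelled
#'   system without treatment credit).
#' @return named numeric of class `sp_referral_rates`.
#' @export
referral_rates <- function(vc_thc, vc_ch, vc_thc_ch = 0, thc_ch = 0, ch_out = 0) {
  r <- c(vc_thc = vc_thc, vc_ch = vc_ch, vc_thc_ch = vc_thc_ch,
         thc_ch = thc_ch, ch_out = ch_out)
  if (any(r < 0 | r > 1)) stop_sp("referral rates must lie in [0,1]")
  if (r[["vc_thc_ch"]] > r[["vc_thc"]] + 1e-12) {
    stop_sp("second-hop mass vc_thc_ch (%.4f) exceeds vc_thc (%.4f)",
            r[["vc_thc_ch"]], r[["vc_thc"]])
  }
  structure(r, class = "sp_referral_rates")
}

CASCADE_POLICIES <- c("additive_credit", "conditional_on_failure", "chain_thc_referral")

check_feasible <- function(q, r, policy) {
  if (policy %in% c("additive_credit", "chain_thc_referral")) {
    out <- list(VC = q[["VC"]] + r[["vc_thc"]] + r[["vc_ch"]],
                THC = q[["THC"]] + r[["thc_ch"]],
                CH = q[["CH"]] + r[["ch_out"]])
  } else {
    out <- list(VC = r[["vc_thc"]] + r[["vc_ch"]],
                THC = r[["thc_ch"]], CH = r[["ch_out"]])
  }
  bad <- names(out)[vapply(out, function(v) v > 1 + 1e-12, logical(1))]
  if (length(bad)) {
    stop_sp("infeasible cascade parameters under %s at tier %s (mass %s)",
            policy, paste(bad, collapse = ", "),
            paste(sprintf("%.4f", unlist(out[bad])), collapse = ", "))
  }
  invisible(TRUE)
}

#' Probability of correct treatment for a given start tier
#'
#' Evaluates the cascade for patients whose first visit is at `tier`, under
#' one of three readings of how observed referral shares combine with
#' treatment success (the field data do not record whether referral was
#' conditioned on treatment failure):
#' \describe{
#'   \item{additive_credit}{referral shares are unconditional masses of the
#'     start-tier population, added to the start tier's own success:
#'     `P(VC) = q_VC + r_vc_ch*q_CH + r_vc_thc*q_THC + r_vc_thc_ch*q_CH`,
#'     `P(THC) = q_THC + r_thc_ch*q_CH`, `P(CH) = q_CH`.}
#'   \item{conditional_on_failure}{referral shares apply to the untreated
#'     remainder and chain recursively:
#'     `P(t) = q_t + (1 - q_t) * sum_u r_tu * P(u)`.}
#'   \item{chain_thc_referral}{as additive_credit, but VC-to-THC transfers
#'     inherit the THC onward-referral rate in place of the explicit
#'     second-hop mass: `P(VC) = q_VC + r_vc_ch*q_CH + r_vc_thc*(q_THC +
#'     r_thc_ch*q_CH)`.}
#' }
#'
#' @param tier `"VC"`, `"THC"` or `"CH"`.
#' @param q an [tier_quality()].
#' @param r an [referral_rates()].
#' @param policy one of `r CASCADE_POLICIES`.
#' @return a single probability.
#' @export
start_tier_probability <- function(tier, q, r,
                                   policy = c("additive_credit",
                                              "conditional_on_failure",
                                              "chain_thc_referral")) {
  policy <- match.arg(policy)
  tier <- match.arg(tier, TIERS)
  check_feasible(q, r, policy)
  qv <- q[["VC"]]; qt <- q[["THC"]]; qc <- q[["CH"]]
  switch(policy,
    additive_credit = switch(tier,
      CH = qc,
      THC = qt + r[["thc_ch"]] * qc,
      VC = qv + r[["vc_ch"]] * qc + r[["vc_thc"]] * qt + r[["vc_thc_ch"]] * qc),
    chain_thc_referral = switch(tier,
      CH = qc,
      THC = qt + r[["thc_ch"]] * qc,
      VC = qv + r[["vc_ch"]] * qc + r[["vc_thc"]] * (qt + r[["thc_ch"]] * qc)),
    conditional_on_failure = {
      p_ch <- qc
      p_thc <- qt + (1 - qt) * r[["thc_ch"]] * p_ch
      p_vc <- qv + (1 - qv) * (r[["vc_thc"]] * p_thc + r[["vc_ch"]] * p_ch)
      switch(tier, CH = p_ch, THC = p_thc, VC = p_vc)
    })
}

cascade_paths <- function(q, r, policy) {
  qv <- q[["VC"]]; qt <- q[["THC"]]; qc <- q[["CH"]]
  path <- function(start, path_str, mass, treated) {
    data.frame(start = start, path = path_str, probability = mass,
               treated = treated, stringsAsFactors = FALSE)
  }
  rows <- switch(policy,
    additive_credit = list(
      path("VC", "VC:treated", qv, TRUE),
      path("VC", "VC>THC:treated", r[["vc_thc"]] * qt, TRUE),
      path("VC", "VC>THC>CH:treated", r[["vc_thc_ch"]] * qc, TRUE),
      path("VC", "VC>CH:treated", r[["vc_ch"]] * qc, TRUE),
      path("THC", "THC:treated", qt, TRUE),
      path("THC", "THC>CH:treated", r[["thc_ch"]] * qc, TRUE),
      path("CH", "CH:treated", qc, TRUE)),
    chain_thc_referral = list(
      path("VC", "VC:treated", qv, TRUE),
      path("VC", "VC>THC:treated", r[["vc_thc"]] * qt, TRUE),
      path("VC", "VC>THC>CH:treated", r[["vc_thc"]] * r[["thc_ch"]] * qc, TRUE),
      path("VC", "VC>CH:treated", r[["vc_ch"]] * qc, TRUE),
      path("THC", "THC:treated", qt, TRUE),
      path("THC", "THC>CH:treated", r[["thc_ch"]] * qc, TRUE),
      path("CH", "CH:treated", qc, TRUE)),
    conditional_on_failure = {
      fv <- 1 - qv; ft <- 1 - qt; fc <- 1 - qc
      list(
        path("VC", "VC:treated", qv, TRUE),
        path("VC", "VC>THC:treated", fv * r[["vc_thc"]] * qt, TRUE),
        path("VC", "VC>THC>CH:treated", fv * r[["vc_thc"]] * ft * r[["thc_ch"]] * qc, TRUE),
        path("VC", "VC>CH:treated", fv * r[["vc_ch"]] * qc, TRUE),
        path("VC", "VC:untreated-exit",
             fv * (1 - r[["vc_thc"]] - r[["vc_ch"]]) +
               fv * r[["vc_thc"]] * ft * (1 - r[["thc_ch"]]) +
               fv * r[["vc_thc"]] * ft * r[["thc_ch"]] * fc +
               fv * r[["vc_ch"]] * fc, FALSE),
        path("THC", "THC:treated", qt, TRUE),
        path("THC", "THC>CH:treated", ft * r[["thc_ch"]] * qc, TRUE),
        path("THC", "THC:untreated-exit",
             ft * (1 - r[["thc_ch"]]) + ft * r[["thc_ch"]] * fc, FALSE),
        path("CH", "CH:treated", qc, TRUE),
        path("CH", "CH:untreated-exit", fc, FALSE))
    })
  paths <- do.call(rbind, rows)
  if (policy != "conditional_on_failure") {
    ## additive-style policies do not model the untreated remainder as a
    ## proper branch; report it as an explicit residual per start tier
    for (t in TIERS) {
      treated_mass <- sum(paths$probability[paths$start == t])
      paths <- rbind(paths, data.frame(start = t, path = sprintf("%s:residual", t),
                                       probability = 1 - treated_mass,
                                       treated = FALSE, stringsAsFactors = FALSE))
    }
  }
  rownames(paths) <- NULL
  paths
}

#' System-level probability of correct treatment
#'
#' Weights the per-start-tier cascade probabilities by the patient sorting
#' distribution: `P(system) = sum_t s_t * P(start = t)`.
#'
#' @param s an [sorting_distribution()].
#' @inheritParams start_tier_probability
#' @return an object of class `sp_cascade_result`: list with
#'   `system_probability`, `per_tier` (named numeric), `paths` (the path
#'   ledger: start tier, path, probability mass, treated flag), `policy`.
#' @export
system_probability <- function(s, q, r,
                               policy = c("additive_credit",
                                          "conditional_on_failure",
                                          "chain_thc_referral")) {
  policy <- match.arg(policy)
  per_tier <- vapply(TIERS, function(t) start_tier_probability(t, q, r, policy),
                     numeric(1))
  paths <- cascade_paths(q, r, policy)
  structure(list(system_probability = sum(s[TIERS] * per_tier),
                 per_tier = per_tier, paths = paths, policy = policy,
                 sorting = s, quality = q, referral = r),
            class = "sp_cascade_result")
}

#' @export
print.sp_cascade_result <- function(x, ...) {
  cat(sprintf("<sp_cascade_result> policy = %s\n", x$policy))
  cat(sprintf("  system probability of correct treatment: %.1f%%\n",
              round_half_up(100 * x$system_probability, 1)))
  cat(sprintf("  per start tier: %s\n",
              paste(sprintf("%s %.1f%%", names(x$per_tier),
                            100 * x$per_tier), collapse = ", ")))
  invisible(x)
}

#' Exhaustive path-enumeration oracle
#'
#' Independent verification of [system_probability()]: walks every patient
#' path explicitly (start tier, optional referral hops, absorbing
#' treated/untreated state) with a generic worklist over a policy-specific
#' transition table, summing the treated mass. Agrees with the analytic
#' closed forms to machine precision.
#'
#' @inheritParams system_probability
#' @return an `sp_cascade_result`.
#' @export
enumerate_paths_oracle <- function(s, q, r,
                                   policy = c("additive_credit",
                                              "conditional_on_failure",
                                              "chain_thc_referral")) {
  policy <- match.arg(policy)
  check_feasible(q, r, policy)
  ## transition table: for a patient present at `state` who arrived along
  ## `route`, the probability of treatment here and the onward referral edges
  edges_from <- function(state, route) {
    if (policy == "conditional_on_failure") {
      base <- switch(state,
                     VC = list(c(THC = unname(r[["vc_thc"]]), CH = unname(r[["vc_ch"]]))),
                     THC = list(c(CH = unname(r[["thc_ch"]]))),
                     CH = list(c(out = unname(r[["ch_out"]]))))
      list(treat = q[[state]], onward = base[[1]], conditional = TRUE)
    } else {
      onward <- if (length(route) == 1) {
        switch(state,
               VC = c(THC = unname(r[["vc_thc"]]), CH = unname(r[["vc_ch"]])),
               THC = c(CH = unname(r[["thc_ch"]])),
               CH = c(out = unname(r[["ch_out"]])))
      } else if (identical(route, c("VC", "THC"))) {
        if (policy == "chain_thc_referral") c(CH = unname(r[["thc_ch"]]))
        else c(CH = unname(r[["vc_thc_ch"]]) / max(unname(r[["vc_thc"]]), .Machine$double.eps))
      } else numeric(0)
      list(treat = q[[state]], onward = onward, conditional = FALSE)
    }
  }
  treated_by_start <- c(VC = 0, THC = 0, CH = 0)
  work <- list(list(start = "VC", state = "VC", route = "VC", mass = 1),
               list(start = "THC", state = "THC", route = "THC", mass = 1),
               list(start = "CH", state = "CH", route = "CH", mass = 1))
  while (length(work)) {
    node <- work[[1]]; work <- work[-1]
    if (node$state == "out" || node$mass <= 0) next
    e <- edges_from(node$state, node$route)
    treated_by_start[node$start] <- treated_by_start[node$start] + node$mass * e$treat
    onward_base <- if (e$conditional) node$mass * (1 - e$treat) else node$mass
    for (dest in names(e$onward)) {
      work[[length(work) + 1]] <- list(start = node$start, state = dest,
                                       route = c(node$route, dest),
                                       mass = onward_base * e$onward[[dest]])
    }
  }
  structure(list(system_probability = sum(s[TIERS] * treated_by_start[TIERS]),
                 per_tier = treated_by_start[TIERS],
                 paths = cascade_paths(q, r, policy), policy = policy,
                 sorting = s, quality = q, referral = r),
            class = "sp_cascade_result")
}

#' Parametric bootstrap interval for the system probability
#'
#' Resamples every cascade input from its sampling distribution — binomial
#' for each treatment and referral rate (given its audit numerator and
#' denominator), multinomial for the sorting distribution — re-evaluates the
#' cascade, and returns the percentile 2.5/97.5 interval. Resamples that are
#' infeasible under the chosen policy are redrawn and logged.
#'
#' @param counts list with elements `quality` (named list per tier:
#'   `c(k, n)`), `referral` (named list per rate name of `c(k, n)`), and
#'   `sorting` (list with `prob` named over tiers and `n`).
#' @param B number of bootstrap replicates (at least 100).
#' @param seed RNG seed; the draw is deterministic given the seed.
#' @param policy cascade policy.
#' @return list with `lower`, `upper`, `point`, `replicates` (numeric vector
#'   of length `B`), `n_redrawn`.
#' @export
bootstrap_cascade_ci <- function(counts, B = 2000, seed = 1,
                                 policy = "additive_credit") {
  if (B < 100) stop_sp("B must be at least 100")
  for (nm in names(counts$quality)) {
    if (counts$quality[[nm]][2] <= 0) stop_sp("zero denominator for quality %s", nm)
  }
  point <- with(counts, system_probability(
    do.call(sorting_distribution, as.list(sorting$prob)),
    tier_quality(quality$VC[1] / quality$VC[2], quality$THC[1] / quality$THC[2],
                 quality$CH[1] / quality$CH[2]),
    do.call(referral_rates, lapply(referral, function(kn) kn[1] / kn[2])),
    policy))$system_probability
  n_redrawn <- 0L
  reps <- with_local_seed(seed, {
    vapply(seq_len(B), function(b) {
      repeat {
        qd <- lapply(counts$quality, function(kn) stats::rbinom(1, kn[2], kn[1] / kn[2]) / kn[2])
        rd <- lapply(counts$referral, function(kn) stats::rbinom(1, kn[2], kn[1] / kn[2]) / kn[2])
        sd_ <- stats::rmultinom(1, counts$sorting$n, counts$sorting$prob)[, 1] /
          counts$sorting$n
        names(sd_) <- names(counts$sorting$prob)
        res <- tryCatch(system_probability(
          do.call(sorting_distribution, as.list(sd_)),
          tier_quality(qd$VC, qd$THC, qd$CH),
          do.call(referral_rates, rd), policy)$system_probability,
          error = function(e) NA_real_)
        if (!is.na(res)) return(res)
        n_redrawn <<- n_redrawn + 1L
        sp_log("cascade", "infeasible bootstrap resample redrawn", "WARN")
      }
    }, numeric(1))
  })
  ci <- stats::quantile(reps, c(0.025, 0.975), names = FALSE, type = 7)
  list(lower = ci[1], upper = ci[2], point = point, replicates = reps,
       n_redrawn = n_redrawn)
}

#' One-parameter sensitivity sweep of the cascade
#'
#' Re-evaluates the system probability over a grid of values for one
#' parameter, all others fixed. Infeasible grid points are flagged, not
#' dropped.
#'
#' @param s,q,r,policy base cascade parameters.
#' @param parameter one of the quality names (`"q_VC"`, `"q_THC"`,
#'   `"q_CH"`), referral names (`"vc_thc"`, `"vc_ch"`, `"vc_thc_ch"`,
#'   `"thc_ch"`, `"ch_out"`), or sorting names (`"s_VC"`, `"s_THC"`,
#'   `"s_CH"`; the other two sorting masses are rescaled proportionally).
#' @param grid numeric vector of values in `[0, 1]`.
#' @return data.frame with `value`, `system_probability`, `feasible`.
#' @export
sensitivity_grid <- function(s, q, r, parameter, grid,
                             policy = "additive_credit") {
  if (any(grid < 0 | grid > 1)) stop_sp("grid values must lie in [0,1]")
  rows <- lapply(grid, function(v) {
    s2 <- s; q2 <- q; r2 <- r
    if (parameter %in% c("q_VC", "q_THC", "q_CH")) {
      q2[[sub("^q_", "", parameter)]] <- v
    } else if (parameter %in% names(r)) {
      r2[[parameter]] <- v
    } else if (parameter %in% c("s_VC", "s_THC", "s_CH")) {
      t <- sub("^s_", "", parameter)
      others <- setdiff(TIERS, t)
      rest <- sum(s[others])
      s2[t] <- v
      s2[others] <- if (rest > 0) s[others] * (1 - v) / rest else (1 - v) / 2
    } else stop_sp("unknown parameter '%s'", parameter)
    res <- tryCatch(system_probability(s2, q2, r2, policy)$system_probability,
                    error = function(e) NA_real_)
    data.frame(value = v, system_probability = res, feasible = !is.na(res))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Load cascade parameters from YAML
#'
#' The packaged default carries the audit's published inputs: sorting
#' 0.39/0.32/0.29, per-tier correct-treatment rates 0.283/0.367/0.323,
#' referral rates VC-to-THC 0.152, VC-to-CH 0.217, second hop 0.022,
#' THC-to-CH 0.143, CH outward 0.032, plus the audit counts behind each rate
#' for the parametric bootstrap.
#'
#' @param path YAML path; defaults to the packaged file.
#' @return list with `sorting`, `quality`, `referral`, `policy`, `counts`.
#' @export
load_cascade_params <- function(path = system.file("extdata", "cascade.yaml",
                                                   package = "spaudit")) {
  cfg <- yaml::read_yaml(path)
  s <- do.call(sorting_distribution, cfg$sorting)
  q <- do.call(tier_quality, cfg$quality)
  r <- do.call(referral_rates, cfg$referral)
  policy <- cfg$policy %||% "additive_credit"
  if (!policy %in% CASCADE_POLICIES) stop_sp("unknown policy '%s'", policy)
  counts <- NULL
  if (!is.null(cfg$counts)) {
    counts <- list(
      quality = lapply(cfg$counts$quality, unlist),
      referral = lapply(cfg$counts$referral, unlist),
      sorting = list(prob = s, n = cfg$counts$sorting_n)
    )
  }
  list(sorting = s, quality = q, referral = r, policy = policy, counts = counts)
}
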