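## Discrimination-experiment trial schema, rate aggregation and a synthetic
## response generator.
##
## Trial tables are plain data.frames with the fixed columns
##   participant, group, point, kind, delta_i_pct, response
## where kind is "metamer" or "dummy" (a catch trial identical to the
## reference; delta_i_pct 0) and response is "different" or "same".

validate_trials <- function(trials) {
  need <- c("participant", "group", "point", "kind", "delta_i_pct",
            "response")
  if (!is.data.frame(trials) || nrow(trials) == 0)
    stop("empty trial table")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop("trial table lacks column(s): ", paste(miss, collapse = ", "))
  badk <- which(!trials$kind %in% c("metamer", "dummy"))
  if (length(badk))
    stop(sprintf("unknown stimulus kind '%s' at row %d", trials$kind[badk[1]],
                 badk[1]))
  badr <- which(!trials$response %in% c("different", "same"))
  if (length(badr))
    stop(sprintf("unknown response token '%s' at row %d",
                 trials$response[badr[1]], badr[1]))
  if (any(trials$delta_i_pct[trials$kind == "dummy"] != 0))
    stop("dummy trials must have delta_i_pct = 0")
  if (!any(trials$kind == "metamer"))
    stop("trial table has no metamer trials")
  invisible(trials)
}

#' Read / write discrimination trial tables
#'
#' @param path CSV file with columns
#'   `participant, group, point, kind, delta_i_pct, response`.
#' @return data.frame of validated trials.
#' @export
read_trials_csv <- function(path) {
  validate_trials(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_trials_csv
#' @param trials trial data.frame.
#' @export
write_trials_csv <- function(trials, path) {
  utils::write.csv(validate_trials(trials), path, row.names = FALSE)
  invisible(path)
}

#' Discrimination rates from a trial table
#'
#' Per stimulus pair (group, point), the rate is
#' `100 * #different / #trials` among metamer trials.  Per-delta averages
#' pool pairs sharing the nominal ipRGC-difference label, and per-group
#' averages pool the group's points; both are unweighted arithmetic means of
#' per-pair rates.  Dummy (catch) trials yield a separate false-alarm rate
#' and are never subtracted from the metamer rates (raw percentages); set
#' `pool_dummies = TRUE` to count them into the per-pair rates instead.
#'
#' @param trials data.frame as in [read_trials_csv()].
#' @param pool_dummies include dummy trials in the per-pair denominators.
#' @return object of class `discrimination_summary`: `per_pair`,
#'   `per_delta`, `per_group` data.frames and `dummy_rate_pct`.
#' @export
discrimination_rates <- function(trials, pool_dummies = FALSE) {
  validate_trials(trials)
  met <- if (pool_dummies) trials else trials[trials$kind == "metamer", ]
  key <- interaction(met$group, met$point, drop = TRUE)
  per_pair <- do.call(rbind, lapply(split(met, key), function(d) {
    data.frame(group = d$group[1], point = d$point[1],
               delta_i_pct = max(d$delta_i_pct),
               n_trials = nrow(d),
               rate_pct = 100 * mean(d$response == "different"))
  }))
  per_pair <- per_pair[order(per_pair$group, per_pair$point), ]
  rownames(per_pair) <- NULL
  agg <- function(f) {
    s <- split(per_pair, f)
    do.call(rbind, lapply(s, function(d)
      data.frame(level = d[[1]][1], mean_rate_pct = mean(d$rate_pct),
                 n_pairs = nrow(d))))
  }
  per_delta <- do.call(rbind, lapply(split(per_pair, per_pair$delta_i_pct),
    function(d) data.frame(delta_i_pct = d$delta_i_pct[1],
                           mean_rate_pct = mean(d$rate_pct),
                           n_pairs = nrow(d))))
  per_group <- do.call(rbind, lapply(split(per_pair, per_pair$group),
    function(d) data.frame(group = d$group[1],
                           mean_rate_pct = mean(d$rate_pct),
                           n_pairs = nrow(d))))
  rownames(per_delta) <- rownames(per_group) <- NULL
  dum <- trials[trials$kind == "dummy", ]
  dummy_rate <- if (nrow(dum)) 100 * mean(dum$response == "different")
                else NA_real_
  structure(list(per_pair = per_pair, per_delta = per_delta,
                 per_group = per_group, dummy_rate_pct = dummy_rate),
            class = "discrimination_summary")
}

#' @export
print.discrimination_summary <- function(x, ...) {
  cat("<discrimination_summary>\nper delta:\n")
  print(x$per_delta)
  cat(sprintf("dummy false-alarm rate: %.1f %%\n", x$dummy_rate_pct))
  invisible(x)
}

#' Trend of discrimination rate with ipRGC difference
#'
#' Least-squares slope and Spearman rank correlation of the per-delta mean
#' rates against the nominal ipRGC difference.  With constant rates the
#' correlation is undefined and flagged as such.
#'
#' @param summary a [discrimination_rates()] result.
#' @return list with `slope` (percentage points per percent delta),
#'   `spearman_rho` (NA when undefined) and `undefined` flag.
#' @export
trend_statistic <- function(summary) {
  stopifnot(inherits(summary, "discrimination_summary"))
  d <- summary$per_delta
  if (nrow(d) < 2) stop("need at least two distinct delta levels")
  slope <- unname(stats::coef(stats::lm(mean_rate_pct ~ delta_i_pct, d))[2])
  if (stats::sd(d$mean_rate_pct) == 0) {
    list(slope = 0, spearman_rho = NA_real_, undefined = TRUE)
  } else {
    rho <- stats::cor(d$delta_i_pct, d$mean_rate_pct, method = "spearman")
    list(slope = slope, spearman_rho = rho, undefined = FALSE)
  }
}

#' Simulate discrimination responses
#'
#' Emulates the experiment design: for every (group, point) pair and
#' participant, `n_trials` metamer presentations and `n_trials` dummy (catch)
#' presentations.  A metamer trial is judged "different" with probability
#' `guess_rate + (1 - guess_rate) * g(slope * delta_i)` where
#' `g(u) = 2 * (logistic(u) - 1/2)` rises from 0 at zero difference towards
#' 1, so a zero slope makes metamer and dummy trials indistinguishable;
#' dummy trials use `guess_rate` alone.  Deterministic given `seed`.
#'
#' @param pairs data.frame with columns `group, point, delta_i_pct`.
#' @param n_participants,n_trials design sizes (defaults 5 and 2).
#' @param guess_rate false-alarm probability in `[0, 1]`.
#' @param slope psychometric steepness per percent of ipRGC difference.
#' @param seed integer seed.
#' @return trial data.frame (see [read_trials_csv()]).
#' @export
simulate_responses <- function(pairs, n_participants = 5, n_trials = 2,
                               guess_rate = 0.1, slope = 1.5, seed = 1) {
  stopifnot(is.data.frame(pairs),
            all(c("group", "point", "delta_i_pct") %in% names(pairs)),
            guess_rate >= 0, guess_rate <= 1)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  design <- expand.grid(trial = seq_len(n_trials),
                        pair = seq_len(nrow(pairs)),
                        participant = seq_len(n_participants))
  di <- pairs$delta_i_pct[design$pair]
  p_met <- guess_rate +
    (1 - guess_rate) * (2 * (stats::plogis(slope * di) - 0.5))
  met <- data.frame(participant = sprintf("P%02d", design$participant),
                    group = pairs$group[design$pair],
                    point = pairs$point[design$pair],
                    kind = "metamer", delta_i_pct = di,
                    response = ifelse(stats::runif(nrow(design)) < p_met,
                                      "different", "same"))
  dum <- data.frame(participant = met$participant,
                    group = met$group, point = met$point,
                    kind = "dummy", delta_i_pct = 0,
                    response = ifelse(stats::runif(nrow(design)) < guess_rate,
                                      "different", "same"))
  out <- rbind(met, dum)
  out <- out[order(out$participant, out$group, out$point), ]
  rownames(out) <- NULL
  out
}
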