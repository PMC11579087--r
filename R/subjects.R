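# Subject-level data containers and the flattened layout used by the
# vectorized objective evaluations.

#' One subject's covariates, dosing and observations
#'
#' @param id subject identifier.
#' @param covariates named list; `weight` (kg) and `vwf` (VWF:Ag, % of
#'   normal) drive the covariate models, `age`/`height`/`blood_group` are
#'   carried along.
#' @param doses data.frame from [dose_events()].
#' @param obs_times observation times (h).
#' @param obs_values observed concentrations (IU/dL), same length.
#' @param true_eta optional simulated random effects (kept by the
#'   generator for recovery checks).
#' @return an object of class `subject_record`.
#' @export
subject_record <- function(id, covariates, doses, obs_times = numeric(),
                           obs_values = numeric(), true_eta = NULL) {
  if (length(obs_times) != length(obs_values)) {
    stop("subject_record: obs_times and obs_values must have equal length")
  }
  structure(list(id = id, covariates = covariates, doses = doses,
                 obs_times = as.numeric(obs_times),
                 obs_values = as.numeric(obs_values),
                 true_eta = true_eta),
            class = "subject_record")
}

#' @export
print.subject_record <- function(x, ...) {
  cat("<subject_record>", x$id, "|", nrow(x$doses), "dose(s),",
      length(x$obs_times), "obs\n")
  invisible(x)
}

#' @export
print.dcm_population <- function(x, ...) {
  nobs <- sum(vapply(x, function(s) length(s$obs_times), 1L))
  cat("<dcm_population>", length(x), "subjects,", nobs, "observations\n")
  invisible(x)
}

as_population <- function(subjects) {
  structure(subjects, class = "dcm_population")
}

#' @export
`[.dcm_population` <- function(x, i) {
  as_population(unclass(x)[i])
}

# Flatten a list of subject_records into parallel vectors:
#   obs rows:  one per observation (obs_subj, obs_time, obs_y)
#   pair rows: one per (observation, dose) combination within a subject
# Cached on the list via an attribute since the layout is static per data
# set while objectives are evaluated thousands of times.
flatten_subjects <- function(subjects) {
  ws <- attr(subjects, "dcmix_flat")
  if (!is.null(ws)) return(ws)
  n <- length(subjects)
  nobs <- vapply(subjects, function(s) length(s$obs_times), 1L)
  ndose <- vapply(subjects, function(s) nrow(s$doses), 1L)
  obs_subj <- rep(seq_len(n), nobs)
  obs_time <- unlist(lapply(subjects, `[[`, "obs_times"), use.names = FALSE)
  obs_y <- unlist(lapply(subjects, `[[`, "obs_values"), use.names = FALSE)
  m <- length(obs_time)

  pr <- vector("list", n)
  off <- c(0L, cumsum(nobs))
  for (i in seq_len(n)) {
    if (nobs[i] == 0L || ndose[i] == 0L) next
    oi <- off[i] + seq_len(nobs[i])
    di <- seq_len(ndose[i])
    pr[[i]] <- list(obs = rep(oi, times = ndose[i]),
                    dose = rep(di, each = nobs[i]))
  }
  pair_obs <- unlist(lapply(pr, `[[`, "obs"), use.names = FALSE)
  pair_subj <- obs_subj[pair_obs]
  pair_dose_t <- unlist(lapply(seq_len(n), function(i) {
    if (is.null(pr[[i]])) return(numeric())
    subjects[[i]]$doses$time[pr[[i]]$dose]
  }), use.names = FALSE)
  pair_amt <- unlist(lapply(seq_len(n), function(i) {
    if (is.null(pr[[i]])) return(numeric())
    subjects[[i]]$doses$amount[pr[[i]]$dose]
  }), use.names = FALSE)
  pair_dur <- unlist(lapply(seq_len(n), function(i) {
    if (is.null(pr[[i]])) return(numeric())
    subjects[[i]]$doses$duration[pr[[i]]$dose]
  }), use.names = FALSE)
  pair_time <- obs_time[pair_obs]

  X <- data.frame(
    weight = vapply(subjects, function(s) as.numeric(s$covariates$weight %||% NA_real_), 1),
    vwf = vapply(subjects, function(s) as.numeric(s$covariates$vwf %||% NA_real_), 1)
  )
  ws <- list(n = n, m = m, nobs = nobs,
             obs_subj = obs_subj, obs_time = obs_time, obs_y = obs_y,
             pair_obs = pair_obs, pair_subj = pair_subj,
             pair_dose_t = pair_dose_t, pair_amt = pair_amt,
             pair_dur = pair_dur, pair_time = pair_time, X = X)
  ws
}

`%||%` <- function(a, b) if (is.null(a)) b else a
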