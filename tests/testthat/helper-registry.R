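## Test helpers: compact registry builders and independent brute-force
## oracles used across the suite.

## Build a registry from a compact event spec: a data.frame with columns
## pid, date, code (discharge_type optional, default "inpatient").
## Patients are created automatically (born `birth`, default 1950-01-01).
tiny_registry <- function(events, birth = "1950-01-01", deaths = NULL,
                          sexes = NULL, window = NULL) {
  events <- as.data.frame(events)
  if (!"discharge_type" %in% names(events))
    events$discharge_type <- "inpatient"
  pids <- sort(unique(as.character(events$pid)))
  patients <- data.frame(
    patient_id = pids,
    sex = if (is.null(sexes)) rep_len(c("male", "female"), length(pids))
          else sexes[pids],
    birth_date = as.Date(birth),
    death_date = if (is.null(deaths)) as.Date(NA)
                 else as.Date(unname(deaths[pids])))
  ev <- data.frame(patient_id = as.character(events$pid),
                   date = as.Date(events$date), code = events$code,
                   discharge_type = events$discharge_type)
  if (is.null(window)) {
    lo <- min(ev$date)
    hi <- max(c(ev$date, patients$death_date), na.rm = TRUE)
    window <- c(lo, hi)
  }
  new_registry(patients, ev, window = window)
}

## Independent brute-force follower count: per patient, sort the first
## occurrences and test strict subsequence order by scanning dates.
brute_followers <- function(reg, codes) {
  fo <- first_occurrences(reg)
  n <- 0L
  for (pid in unique(reg$patients$patient_id)) {
    sub <- fo[fo$patient_id == pid]
    dates <- as.numeric(sub$first_date)[match(codes, sub$code)]
    if (anyNA(dates)) next
    if (all(diff(dates) > 0)) n <- n + 1L
  }
  n
}

## Exhaustive trajectory enumeration oracle: depth-first over all chains of
## pairs, brute-force follower counting, no pruning shortcuts.
brute_trajectories <- function(pair_df, reg, min_followers, max_length = 6L) {
  pair_df <- as.data.frame(pair_df)
  out <- list()
  recurse <- function(chain) {
    if (length(chain) >= 2L) {
      n <- brute_followers(reg, chain)
      if (n < min_followers) return()  # anti-monotone: safe to stop
      out[[length(out) + 1L]] <<- list(chain = chain, n = n)
    }
    if (length(chain) >= max_length) return()
    nxt <- pair_df$d2[pair_df$d1 == chain[length(chain)]]
    for (nx in setdiff(nxt, chain)) recurse(c(chain, nx))
  }
  for (i in seq_len(nrow(pair_df))) recurse(c(pair_df$d1[i], pair_df$d2[i]))
  if (!length(out)) return(data.frame(trajectory = character(),
                                      n_followers = integer()))
  res <- data.frame(
    trajectory = vapply(out, function(x) paste(x$chain, collapse = "->"), ""),
    n_followers = vapply(out, function(x) x$n, integer(1)))
  res <- unique(res)
  res[order(res$trajectory), , drop = FALSE]
}

## Random small registry + pair graph for oracle-equivalence property tests.
random_small_instance <- function(seed, n_patients = 200L, n_codes = 6L) {
  set.seed(seed)
  codes <- sprintf("%s%02d", LETTERS[seq_len(n_codes)], seq_len(n_codes))
  pids <- sprintf("p%03d", seq_len(n_patients))
  n_ev <- stats::rpois(n_patients, 3)
  idx <- rep(seq_len(n_patients), n_ev)
  ev <- data.frame(
    pid = pids[idx],
    date = as.Date("2000-01-01") + sample.int(6000, length(idx), replace = TRUE),
    code = sample(codes, length(idx), replace = TRUE))
  reg <- tiny_registry(ev)
  all_pairs <- expand.grid(d1 = codes, d2 = codes,
                           stringsAsFactors = FALSE)
  all_pairs <- all_pairs[all_pairs$d1 < all_pairs$d2, ]  # no reverses
  pair_df <- all_pairs[stats::runif(nrow(all_pairs)) < 0.4, , drop = FALSE]
  list(registry = reg, pairs = pair_df)
}
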