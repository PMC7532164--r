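#' @name trajectory-network
#' @title Merged disease trajectory networks and export
#'
#' @description Linear trajectories sharing codes are merged into a single
#' directed graph: nodes are ICD-10 codes annotated with chapter, unique
#' patient count and 5-year mortality; edges are the underlying directional
#' pairs annotated with their statistics and length-2 follower counts.
#' Networks serialise to Cytoscape JSON (the `elements` format read by
#' Cytoscape Desktop and cytoscape.js) and to delimited edge tables, always
#' passing through privacy suppression: no serialised count may refer to
#' fewer than `min_patients` (default 5) individuals.
NULL

#' Merge linear trajectories into a disease trajectory network
#'
#' Takes the union of all codes (nodes) and all adjacent pairs (edges) over
#' the trajectories. Edge statistics come from the directional-pair table
#' (attached by [build_trajectories()] or passed explicitly) and are
#' independent of how many trajectories share the edge; the edge follower
#' count and mean gap come from the corresponding length-2 trajectory when
#' present. Node patient counts and mortality are computed from the registry
#' when one is supplied.
#'
#' @param trajectories a `trajectory_set`.
#' @param pairs optional directional-pair table (defaults to the attribute
#'   attached to `trajectories`).
#' @param reg optional `registry` for node annotations.
#' @param provenance optional named list stored on the network (thresholds,
#'   seed, ...).
#' @return a `trajectory_network`: list with `nodes` (code, chapter,
#'   n_patients, mortality_5y), `edges` (d1, d2, n_followers, rr,
#'   p_direction, p_cooccurrence, mean_gap_years) and `provenance`.
#' @export
merge_network <- function(trajectories, pairs = NULL, reg = NULL,
                          provenance = list()) {
  if (is.null(pairs)) pairs <- attr(trajectories, "pairs")
  edge_list <- list()
  for (i in seq_len(nrow(trajectories))) {
    cs <- trajectories$codes[[i]]
    if (length(cs) >= 2L)
      edge_list[[i]] <- data.table::data.table(d1 = cs[-length(cs)],
                                               d2 = cs[-1L])
  }
  edges <- if (length(edge_list))
    unique(data.table::rbindlist(edge_list)) else
    data.table::data.table(d1 = character(), d2 = character())
  stat_cols <- c("rr", "p_direction", "p_cooccurrence")
  if (!is.null(pairs) && nrow(pairs)) {
    pstat <- data.table::as.data.table(pairs)
    keep <- intersect(c("d1", "d2", stat_cols), names(pstat))
    edges <- merge(edges, pstat[, keep, with = FALSE],
                   by = c("d1", "d2"), all.x = TRUE)
  }
  for (cc in setdiff(stat_cols, names(edges))) edges[, (cc) := NA_real_]
  ## follower count + mean gap of the matching length-2 trajectory
  len2 <- trajectories[trajectories$length == 2L]
  if (nrow(len2)) {
    l2 <- data.table::data.table(
      d1 = vapply(len2$codes, `[`, "", 1L),
      d2 = vapply(len2$codes, `[`, "", 2L),
      n_followers = len2$n_followers,
      mean_gap_years = if ("edge_gap_years" %in% names(len2))
        vapply(len2$edge_gap_years, `[`, numeric(1), 1L) else NA_real_)
    edges <- merge(edges, l2, by = c("d1", "d2"), all.x = TRUE)
  } else {
    edges[, `:=`(n_followers = NA_integer_, mean_gap_years = NA_real_)]
  }
  codes <- sort(unique(c(edges$d1, edges$d2,
                         unlist(trajectories$codes))))
  nodes <- data.table::data.table(code = codes,
                                  chapter = icd10_chapter(codes),
                                  n_patients = NA_integer_,
                                  mortality_5y = NA_integer_)
  if (!is.null(reg)) {
    if (DEATH_CODE %in% codes && !(DEATH_CODE %in% reg$events$code))
      reg <- inject_death_events(reg)
    fo <- first_occurrences(reg)[code %in% codes]
    fo <- merge(fo, reg$patients[, .(patient_id, death_date)],
                by = "patient_id")
    stats <- fo[, .(n_patients = .N,
                    mortality_5y = sum(!is.na(death_date) &
                      as.numeric(death_date - first_date) <=
                        5 * DAYS_PER_YEAR)),
                by = code]
    nodes <- merge(nodes[, .(code, chapter)], stats, by = "code",
                   all.x = TRUE)
    nodes[is.na(n_patients), `:=`(n_patients = 0L, mortality_5y = 0L)]
  }
  data.table::setorder(nodes, code)
  data.table::setorder(edges, d1, d2)
  structure(list(nodes = nodes[], edges = edges[], provenance = provenance),
            class = "trajectory_network")
}

#' @export
print.trajectory_network <- function(x, ...) {
  cat(sprintf("<trajectory_network> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Select a node's neighbourhood in a trajectory network
#'
#' @param network a `trajectory_network`.
#' @param code node code; must exist in the network.
#' @param mode `"incoming"` (edges ending at the code), `"outgoing"` (edges
#'   starting at it), `"both"`, or `"inverse"` (the complement of the
#'   `"both"` selection: all other edges plus the non-neighbour nodes).
#' @return list with `nodes` and `edges` (subsets of the network tables).
#' @export
neighbourhood <- function(network, code,
                          mode = c("both", "incoming", "outgoing", "inverse")) {
  mode <- match.arg(mode)
  stopifnot(inherits(network, "trajectory_network"))
  if (!code %in% network$nodes$code)
    stop("code not in network: ", code, call. = FALSE)
  e <- network$edges
  sel <- switch(mode,
    incoming = e$d2 == code,
    outgoing = e$d1 == code,
    both = e$d1 == code | e$d2 == code,
    inverse = !(e$d1 == code | e$d2 == code))
  edges <- e[sel]
  if (mode == "inverse") {
    both_nodes <- unique(c(code, e$d1[e$d1 == code | e$d2 == code],
                           e$d2[e$d1 == code | e$d2 == code]))
    nodes <- network$nodes[!network$nodes$code %in% both_nodes]
  } else {
    nodes <- network$nodes[network$nodes$code %in%
                             unique(c(code, edges$d1, edges$d2))]
  }
  list(nodes = nodes, edges = edges)
}

#' Filter trajectories or network edges by attribute ranges
#'
#' Retains rows whose attributes fall inside all supplied closed ranges;
#' filters compose commutatively. On a `trajectory_set` the length and
#' follower ranges apply per trajectory and the RR range to every edge of
#' the trajectory; on a `trajectory_network` the RR and follower ranges
#' apply per edge (isolated nodes are dropped).
#'
#' @param x a `trajectory_set` or `trajectory_network`.
#' @param sex `"all"`, `"male"` or `"female"`; anything but `"all"` requires
#'   `x` to carry a matching `sex` attribute (set when mining was
#'   sex-stratified) and errors otherwise.
#' @param length_range,rr_range,follower_range closed numeric ranges
#'   `c(min, max)`.
#' @return the filtered object, same class as `x`.
#' @export
apply_filters <- function(x, sex = "all",
                          length_range = c(2, Inf),
                          rr_range = c(-Inf, Inf),
                          follower_range = c(0, Inf)) {
  for (r in list(length_range, rr_range, follower_range))
    if (length(r) != 2L || r[1] > r[2])
      stop("inverted or malformed range", call. = FALSE)
  if (sex != "all") {
    tag <- attr(x, "sex")
    if (is.null(tag) || tag != sex)
      stop("object does not carry results stratified for sex = ", sex,
           call. = FALSE)
  }
  if (inherits(x, "trajectory_network")) {
    e <- x$edges
    keep <- (is.na(e$rr) | (e$rr >= rr_range[1] & e$rr <= rr_range[2])) &
      (is.na(e$n_followers) |
         (e$n_followers >= follower_range[1] &
            e$n_followers <= follower_range[2]))
    e <- e[keep]
    n <- x$nodes[x$nodes$code %in% unique(c(e$d1, e$d2))]
    return(structure(list(nodes = n, edges = e, provenance = x$provenance),
                     class = "trajectory_network"))
  }
  stopifnot(inherits(x, "trajectory_set"))
  pairs <- attr(x, "pairs")
  keep <- x$length >= length_range[1] & x$length <= length_range[2] &
    x$n_followers >= follower_range[1] & x$n_followers <= follower_range[2]
  if (!is.null(pairs) && nrow(pairs) && "rr" %in% names(pairs) &&
      any(is.finite(rr_range))) {
    rr_of <- stats::setNames(pairs$rr, paste(pairs$d1, pairs$d2, sep = "->"))
    edge_ok <- vapply(x$codes, function(cs) {
      rrs <- rr_of[paste(cs[-length(cs)], cs[-1L], sep = "->")]
      all(is.na(rrs) | (rrs >= rr_range[1] & rrs <= rr_range[2]))
    }, logical(1))
    keep <- keep & edge_ok
  }
  as_trajectory_set(x[keep], pairs)
}

#' Privacy suppression of small patient counts
#'
#' Removes any trajectory, edge or node whose patient count falls below
#' `min_patients`, and masks (sets to `NA`) mortality counts in
#' `(0, min_patients)`. Serialisation ([export_cyjs()], [export_csv()])
#' applies this by default, mirroring summary-data release rules that only
#' disclose information assigned to at least five patients.
#'
#' @param x a `trajectory_set` or `trajectory_network`.
#' @param min_patients suppression threshold (default 5); 0 is the identity.
#' @return the suppressed object.
#' @export
suppress_small_counts <- function(x, min_patients = 5L) {
  if (min_patients <= 0) return(x)
  if (inherits(x, "trajectory_network")) {
    e <- x$edges[is.na(n_followers) | n_followers >= min_patients]
    n <- x$nodes[is.na(n_patients) | n_patients >= min_patients]
    e <- e[d1 %in% n$code & d2 %in% n$code]
    n <- data.table::copy(n)
    n[!is.na(mortality_5y) & mortality_5y > 0 &
        mortality_5y < min_patients, mortality_5y := NA_integer_]
    return(structure(list(nodes = n, edges = e,
                          provenance = x$provenance),
                     class = "trajectory_network"))
  }
  stopifnot(inherits(x, "trajectory_set"))
  out <- x[x$n_followers >= min_patients]
  if ("mortality_5y" %in% names(out))
    out[!is.na(mortality_5y) & mortality_5y > 0 & mortality_5y < min_patients,
        mortality_5y := NA_integer_]
  as_trajectory_set(out, attr(x, "pairs"))
}

## ---------------------------------------------------------------------
## serialisation

#' Export a trajectory network as Cytoscape JSON
#'
#' Writes the standard `elements` structure (`nodes` / `edges` lists of
#' `data` objects) consumed by Cytoscape Desktop and cytoscape.js. Node data
#' carry `id` (the code), `chapter`, `n_patients`, `mortality_5y`; edge data
#' carry `id` ("D1->D2"), `source`, `target`, `n_followers`, `rr`,
#' `p_direction`, `p_cooccurrence`, `mean_gap_years`. Output is byte-stable
#' for identical inputs (sorted elements, fixed formatting). Privacy
#' suppression runs first unless `min_patients = 0`.
#'
#' @param network a `trajectory_network`.
#' @param path output file path (conventionally `.cyjs`).
#' @param min_patients suppression threshold (default 5).
#' @return invisibly, `path`.
#' @export
export_cyjs <- function(network, path, min_patients = 5L) {
  stopifnot(inherits(network, "trajectory_network"))
  network <- suppress_small_counts(network, min_patients)
  node_el <- lapply(seq_len(nrow(network$nodes)), function(i) {
    r <- network$nodes[i]
    list(data = list(id = r$code, chapter = r$chapter,
                     n_patients = r$n_patients,
                     mortality_5y = r$mortality_5y))
  })
  edge_el <- lapply(seq_len(nrow(network$edges)), function(i) {
    r <- network$edges[i]
    list(data = list(id = paste0(r$d1, "->", r$d2),
                     source = r$d1, target = r$d2,
                     n_followers = r$n_followers, rr = r$rr,
                     p_direction = r$p_direction,
                     p_cooccurrence = r$p_cooccurrence,
                     mean_gap_years = r$mean_gap_years))
  })
  obj <- list(format_version = "1.0",
              generated_by = "trajmine",
              elements = list(nodes = node_el, edges = edge_el),
              provenance = network$provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a Cytoscape JSON file written by [export_cyjs()]
#'
#' @param path `.cyjs` file path.
#' @return a `trajectory_network`.
#' @export
read_cyjs <- function(path) {
  j <- jsonlite::read_json(path)
  grab <- function(x, f, cast) {
    v <- x$data[[f]]
    if (is.null(v)) cast(NA) else cast(v)
  }
  nodes <- data.table::rbindlist(lapply(j$elements$nodes, function(x)
    data.table::data.table(code = grab(x, "id", as.character),
                           chapter = grab(x, "chapter", as.character),
                           n_patients = grab(x, "n_patients", as.integer),
                           mortality_5y = grab(x, "mortality_5y", as.integer))))
  edges <- data.table::rbindlist(lapply(j$elements$edges, function(x)
    data.table::data.table(
      d1 = grab(x, "source", as.character),
      d2 = grab(x, "target", as.character),
      rr = grab(x, "rr", as.numeric),
      p_direction = grab(x, "p_direction", as.numeric),
      p_cooccurrence = grab(x, "p_cooccurrence", as.numeric),
      n_followers = grab(x, "n_followers", as.integer),
      mean_gap_years = grab(x, "mean_gap_years", as.numeric))))
  if (!nrow(nodes))
    nodes <- data.table::data.table(code = character(), chapter = character(),
                                    n_patients = integer(),
                                    mortality_5y = integer())
  if (!nrow(edges))
    edges <- data.table::data.table(d1 = character(), d2 = character(),
                                    rr = numeric(), p_direction = numeric(),
                                    p_cooccurrence = numeric(),
                                    n_followers = integer(),
                                    mean_gap_years = numeric())
  data.table::setorder(nodes, code)
  data.table::setorder(edges, d1, d2)
  structure(list(nodes = nodes, edges = edges,
                 provenance = j$provenance),
            class = "trajectory_network")
}

#' Export edges or trajectories as a delimited table
#'
#' One row per network edge (or per trajectory for a `trajectory_set`) with
#' the full statistics columns. Privacy suppression runs first. Optional
#' provenance strings are written as leading `#` comment lines.
#'
#' @param x a `trajectory_network` or `trajectory_set`.
#' @param path output CSV path.
#' @param min_patients suppression threshold (default 5).
#' @param provenance optional character vector of comment lines.
#' @return invisibly, `path`.
#' @export
export_csv <- function(x, path, min_patients = 5L, provenance = NULL) {
  x <- suppress_small_counts(x, min_patients)
  tab <- if (inherits(x, "trajectory_network")) x$edges
  else {
    flat <- data.table::as.data.table(x)
    flat[, codes := NULL]
    if ("edge_gap_years" %in% names(flat))
      flat[, edge_gap_years := vapply(x$edge_gap_years, function(g)
        paste(format(g, digits = 10, trim = TRUE), collapse = "|"), "")]
    flat
  }
  if (length(provenance)) {
    writeLines(paste0("# ", provenance), path)
    data.table::fwrite(tab, path, append = TRUE, col.names = TRUE)
  } else data.table::fwrite(tab, path)
  invisible(path)
}
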