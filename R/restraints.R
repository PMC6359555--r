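# Distance-restraint tables: a plain tab-separated dialect with columns
#   id  group1  group2  d0_nm  kind
# where group1/group2 are comma-separated 0-based atom indices (group2 holds
# exactly one atom by default) and kind is "noe" or "xlink". Lines starting
# with '#' and blank lines are ignored.

#' Create a distance-restraint record
#'
#' @param id integer record id (unique within a table).
#' @param group1 integer vector of candidate atom indices, 0-based.
#' @param group2 integer vector with exactly one atom index, 0-based.
#' @param d0 target distance in nm (> 0).
#' @param kind `"noe"` or `"xlink"`.
#' @return A list of class `pathmd_restraint`.
#' @export
restraint_record <- function(id, group1, group2, d0, kind = "noe") {
  group1 <- as.integer(group1); group2 <- as.integer(group2)
  if (length(group1) < 1 || length(group2) < 1)
    stop("restraint groups must be non-empty")
  if (length(intersect(group1, group2)) > 0)
    stop("restraint groups must be disjoint")
  if (!is.finite(d0) || d0 <= 0) stop("d0 must be > 0")
  if (!kind %in% c("noe", "xlink")) stop("unknown restraint kind: ", kind)
  structure(list(id = as.integer(id), group1 = group1, group2 = group2,
                 d0 = as.numeric(d0), kind = kind),
            class = "pathmd_restraint")
}

#' Read a restraint table
#'
#' Parses the package's tab-separated restraint dialect. Atom indices in files
#' are 0-based (note: unlike the 1-based convention of most MD tooling).
#'
#' @param path file path.
#' @return A `pathmd_restraints` list of [restraint_record()]s.
#' @export
parse_restraint_table <- function(path) {
  lines <- readLines(path)
  recs <- list()
  ids <- integer(0)
  for (ln in seq_along(lines)) {
    raw <- trimws(lines[ln])
    if (raw == "" || startsWith(raw, "#")) next
    fields <- strsplit(raw, "\t", fixed = TRUE)[[1]]
    if (length(fields) != 5)
      stop(sprintf("line %d: expected 5 tab-separated fields, got %d",
                   ln, length(fields)))
    idx <- function(x) {
      v <- suppressWarnings(as.integer(strsplit(x, ",", fixed = TRUE)[[1]]))
      if (anyNA(v)) stop(sprintf("line %d: malformed atom indices '%s'", ln, x))
      v
    }
    id <- suppressWarnings(as.integer(fields[1]))
    if (is.na(id)) stop(sprintf("line %d: malformed id '%s'", ln, fields[1]))
    if (id %in% ids) stop(sprintf("line %d: duplicate id %d", ln, id))
    d0 <- suppressWarnings(as.numeric(fields[4]))
    if (is.na(d0) || d0 <= 0)
      stop(sprintf("line %d: d0 must be a positive number, got '%s'",
                   ln, fields[4]))
    rec <- tryCatch(
      restraint_record(id, idx(fields[2]), idx(fields[3]), d0, fields[5]),
      error = function(e) stop(sprintf("line %d: %s", ln, conditionMessage(e))))
    ids <- c(ids, id)
    recs[[length(recs) + 1]] <- rec
  }
  structure(recs, class = "pathmd_restraints")
}

#' Write a restraint table
#'
#' @param restraints a `pathmd_restraints` list or list of records.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_restraint_table <- function(restraints, path) {
  lines <- c("# pathmd restraint table",
             "# id\tgroup1\tgroup2\td0_nm\tkind (atom indices 0-based)")
  for (r in restraints) {
    lines <- c(lines, sprintf("%d\t%s\t%s\t%.6g\t%s", r$id,
                              paste(r$group1, collapse = ","),
                              paste(r$group2, collapse = ","),
                              r$d0, r$kind))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.pathmd_restraints <- function(x, ...) {
  cat(sprintf("<pathmd_restraints: %d record(s)>\n", length(x)))
  for (r in head(x, 10))
    cat(sprintf("  #%d  {%s} -- {%s}  d0 = %g nm  [%s]\n", r$id,
                paste(r$group1, collapse = ","),
                paste(r$group2, collapse = ","), r$d0, r$kind))
  if (length(x) > 10) cat("  ...\n")
  invisible(x)
}

#' Effective restraint distance
#'
#' For group restraints the distance is the minimum over group-1 atoms of the
#' distance to the (single) group-2 atom; the restraint vector is
#' `q12 = q(realizing group-1 atom) - q(group-2 atom)`.
#'
#' @param q coordinate matrix (`n_particles` rows, `dimension` columns) or a
#'   flat vector with `dim` columns implied by `dimension`.
#' @param record a [restraint_record()].
#' @param dimension coordinate dimension if `q` is a flat vector.
#' @return `list(d12, q12, pair)` where `pair` holds the realizing 0-based
#'   (group1, group2) atoms, plus `coincident = TRUE` if `d12 == 0`.
#' @export
effective_distance <- function(q, record, dimension = NULL) {
  if (!is.matrix(q)) {
    if (is.null(dimension)) stop("supply a coordinate matrix or `dimension`")
    q <- matrix(q, ncol = dimension, byrow = TRUE)
  }
  n <- nrow(q)
  if (any(record$group1 >= n) || any(record$group2 >= n) ||
      any(c(record$group1, record$group2) < 0))
    stop("restraint references an atom index outside the system")
  q2 <- q[record$group2 + 1L, , drop = TRUE]
  d <- apply(q[record$group1 + 1L, , drop = FALSE], 1,
             function(row) sqrt(sum((row - q2)^2)))
  best <- which.min(d)
  a1 <- record$group1[best]
  list(d12 = d[best],
       q12 = q[a1 + 1L, ] - q2,
       pair = c(a1, record$group2[1]),
       coincident = d[best] == 0)
}

#' Restraint-fulfillment report
#'
#' Computes the per-restraint difference series Delta(t) = d(t) - d0 together
#' with its minimum, mean, and the fraction of frames with Delta <= 0
#' (the restraint counted as fulfilled).
#'
#' @param trajectory a `pathmd_trajectory` (from [run_trajectory()]) or a
#'   matrix of frame coordinates (frames in rows, flat coordinates in columns).
#' @param restraints a `pathmd_restraints` list.
#' @param dimension coordinate dimension (taken from the trajectory if given).
#' @param times frame times (taken from the trajectory if given).
#' @return An object of class `pathmd_fulfillment`: a list with `delta`
#'   (frames x restraints matrix), `times` and a `summary` data frame with
#'   columns `id`, `min`, `mean`, `fulfilled_fraction`.
#' @export
fulfillment_report <- function(trajectory, restraints, dimension = NULL,
                               times = NULL) {
  if (inherits(trajectory, "pathmd_trajectory")) {
    frames <- trajectory$q
    dimension <- trajectory$system$dimension
    times <- trajectory$data$t
  } else {
    frames <- trajectory
    if (is.null(dimension)) stop("supply `dimension` for raw coordinate frames")
    if (is.null(times)) times <- seq_len(nrow(frames)) - 1
  }
  nf <- nrow(frames)
  delta <- matrix(NA_real_, nf, length(restraints))
  for (f in seq_len(nf)) {
    qm <- matrix(frames[f, ], ncol = dimension, byrow = TRUE)
    for (r in seq_along(restraints))
      delta[f, r] <- effective_distance(qm, restraints[[r]])$d12 -
        restraints[[r]]$d0
  }
  ids <- vapply(restraints, `[[`, integer(1), "id")
  colnames(delta) <- paste0("r", ids)
  summary <- data.frame(id = ids,
                        min = apply(delta, 2, min),
                        mean = colMeans(delta),
                        fulfilled_fraction = colMeans(delta <= 0),
                        row.names = NULL)
  structure(list(delta = delta, times = times, summary = summary),
            class = "pathmd_fulfillment")
}

#' @export
print.pathmd_fulfillment <- function(x, ...) {
  cat(sprintf("<pathmd_fulfillment: %d restraint(s), %d frame(s)>\n",
              ncol(x$delta), nrow(x$delta)))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Write a fulfillment report
#'
#' Writes the Delta(t) series as CSV (`restraint_id,t,delta_nm`) and the
#' min/mean/fulfilled-fraction summary as JSON.
#'
#' @param report a `pathmd_fulfillment`.
#' @param csv_path,json_path output paths (either may be `NULL` to skip).
#' @return invisibly, the report.
#' @export
write_fulfillment <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    ids <- sub("^r", "", colnames(report$delta))
    long <- do.call(rbind, lapply(seq_along(ids), function(j)
      data.frame(restraint_id = as.integer(ids[j]), t = report$times,
                 delta_nm = report$delta[, j])))
    utils::write.csv(long, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    s <- report$summary
    out <- lapply(seq_len(nrow(s)), function(i)
      list(min = s$min[i], mean = s$mean[i],
           fulfilled_fraction = s$fulfilled_fraction[i]))
    names(out) <- as.character(s$id)
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
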