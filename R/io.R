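# Plain-text format plumbing shared by the CLI and the tests. CSV dialect
# is fixed (comma, header row, '.' decimal, UTF-8) so fixtures are
# byte-stable across runs.

#' Write / read boundary trajectories as JSON-lines
#'
#' One record per cell per frame: `{"cell_id": ..., "time_min": ...,
#' "vertices": [[x, y], ...]}`. The reader returns a list of cells, each a
#' time-ordered list of [boundary_polygon()]s.
#'
#' @param traj either an `fw_simulation` (all cells, all frames) or a list
#'   of [boundary_polygon()]s.
#' @param path output file.
#' @export
write_trajectory_jsonl <- function(traj, path) {
  polys <- flatten_trajectory(traj)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (p in polys) {
    rec <- list(cell_id = attr(p, "cell_id"),
                time_min = attr(p, "frame_time"),
                vertices = unclass(p)[, , drop = FALSE])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_trajectory_jsonl
#' @export
read_trajectory_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no records in ", path)
  polys <- lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) stop("malformed record at line ", i,
                                             " of ", path, ": ", conditionMessage(e)))
    if (is.null(rec$cell_id) || is.null(rec$time_min) || is.null(rec$vertices))
      stop("malformed record at line ", i, " of ", path,
           ": needs cell_id, time_min, vertices")
    boundary_polygon(rec$vertices, frame_time = rec$time_min,
                     cell_id = rec$cell_id)
  })
  split_by_cell(polys)
}

#' Write / read boundary trajectories as tidy CSV
#'
#' Columns: cell_id, time_min, vertex_index, x, y.
#'
#' @inheritParams write_trajectory_jsonl
#' @export
write_trajectory_csv <- function(traj, path) {
  polys <- flatten_trajectory(traj)
  df <- do.call(rbind, lapply(polys, function(p) {
    v <- unclass(p)
    data.frame(cell_id = attr(p, "cell_id"), time_min = attr(p, "frame_time"),
               vertex_index = seq_len(nrow(v)), x = v[, 1], y = v[, 2])
  }))
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  need <- c("cell_id", "time_min", "vertex_index", "x", "y")
  if (!all(need %in% names(df)))
    stop("trajectory CSV needs columns: ", paste(need, collapse = ", "))
  polys <- list()
  for (key in split(seq_len(nrow(df)),
                    interaction(df$cell_id, df$time_min, drop = TRUE))) {
    sub <- df[key, ]
    sub <- sub[order(sub$vertex_index), ]
    polys[[length(polys) + 1L]] <-
      boundary_polygon(cbind(sub$x, sub$y), frame_time = sub$time_min[1],
                       cell_id = sub$cell_id[1])
  }
  split_by_cell(polys)
}

flatten_trajectory <- function(traj) {
  if (inherits(traj, "fw_simulation")) {
    st <- traj$state
    polys <- list()
    for (fi in seq_along(st$frames))
      for (ci in seq_along(st$cells))
        polys[[length(polys) + 1L]] <-
          boundary_polygon(st$frames[[fi]][st$cells[[ci]], , drop = FALSE],
                           frame_time = st$frame_times[fi], cell_id = ci)
    polys
  } else if (is_boundary_polygon(traj)) list(traj)
  else if (is.list(traj)) lapply(traj, function(p)
    if (is_boundary_polygon(p)) p else boundary_polygon(p))
  else stop("unsupported trajectory object")
}

split_by_cell <- function(polys) {
  ids <- vapply(polys, function(p) as.character(attr(p, "cell_id")), character(1))
  out <- lapply(split(polys, ids), function(ps) {
    ps[order(vapply(ps, function(p) attr(p, "frame_time"), numeric(1)))]
  })
  out[order(suppressWarnings(as.numeric(names(out))), names(out))]
}

#' Read / write signal traces as CSV (time_min, value)
#'
#' @param trace a [signal_trace()].
#' @param path file path.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(data.frame(time_min = trace_times(trace),
                              value = trace$values),
                   path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trace_csv
#' @param label label for the trace read back.
#' @export
read_trace_csv <- function(path, label = basename(path)) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  if (!all(c("time_min", "value") %in% names(df)))
    stop("trace CSV needs columns time_min, value: ", path)
  dts <- diff(df$time_min)
  if (length(dts) && max(abs(dts - dts[1])) > 1e-9)
    stop("trace is not uniformly sampled: ", path)
  signal_trace(df$value, dts[1], label = label)
}

#' Read / write grayscale images as plain CSV matrices
#'
#' Plain-text stand-in for TIFF stacks (no TIFF reader is available in the
#' supported R stack): one CSV per image, no header, rows = y, columns = x.
#'
#' @param image numeric matrix.
#' @param path file path.
#' @export
write_image_csv <- function(image, path) {
  utils::write.table(as.matrix(image), path, sep = ",", row.names = FALSE,
                     col.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_image_csv
#' @export
read_image_csv <- function(path) {
  as.matrix(utils::read.csv(path, header = FALSE, fileEncoding = "UTF-8"))
}

#' Parse a run configuration file
#'
#' Flat `key: value` lines grouped under `[params]`, `[program]` and
#' `[genotype]` / `[run]` section headers; `#` starts a comment. Unknown
#' keys are rejected (fail fast). Values are parsed as numerics where
#' possible; vector values are comma-separated.
#'
#' @param path config file path.
#' @return list with elements `params` ([model_params()]), `program`
#'   ([phase_program()]), `run` (genotype, mode, seed, out, patch geometry).
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  section <- "run"
  sections <- list(params = list(), program = list(), run = list())
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("\\[|\\]", "", ln)
      if (!section %in% names(sections))
        stop("unknown config section [", section, "]")
    } else {
      kv <- strsplit(ln, ":", fixed = TRUE)[[1]]
      if (length(kv) < 2L) stop("malformed config line: ", ln)
      key <- trimws(kv[1])
      val <- trimws(paste(kv[-1], collapse = ":"))
      num <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
      if (!any(is.na(num))) val <- num
      sections[[section]][[key]] <- val
    }
  }
  params <- do.call(model_params,
                    check_keys(sections$params, names(formals(model_params)), "params"))
  program <- do.call(phase_program,
                     check_keys(sections$program, names(formals(phase_program)), "program"))
  run_known <- c("genotype", "mode", "seed", "out", "n_rows", "n_cols",
                 "edge_len", "verts_per_edge", "total_minutes")
  run <- check_keys(sections$run, run_known, "run")
  list(params = params, program = program, run = run)
}

check_keys <- function(given, known, section) {
  bad <- setdiff(names(given), known)
  if (length(bad))
    stop("unknown key(s) in [", section, "]: ", paste(bad, collapse = ", "))
  given
}
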