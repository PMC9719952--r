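# File formats: BIDS-style events/confounds TSV, delimited numeric
# matrices with label headers, subject-label and atlas tables. All writers
# emit a provenance comment header ("# ..."), all readers skip it.

provenance_header <- function(kind, seed = NULL) {
  c(
    sprintf("# switchconn %s v%s", kind, as.character(utils::packageVersion("switchconn"))),
    if (!is.null(seed)) sprintf("# seed=%s", format(seed))
  )
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Write / read a labelled numeric matrix
#'
#' Matrices are stored as delimited text with a provenance comment header, a
#' header row of column labels, and (when row names are present) a leading
#' column of row labels. Values are written with 17 significant digits so a
#' write/read round trip is bitwise exact. `read_matrix()` sniffs the
#' delimiter (tab or comma), validates that rows are rectangular and
#' numeric, and reports the offending row/column otherwise.
#'
#' @param x Numeric matrix.
#' @param path File path.
#' @param seed Optional seed recorded in the provenance header.
#' @param expected_labels Optional label vector; the parsed matrix must have
#'   one column per label.
#' @return `read_matrix()` returns the numeric matrix with dimnames.
#' @export
write_matrix <- function(x, path, seed = NULL) {
  x <- as.matrix(x)
  cols <- colnames(x) %||% sprintf("V%d", seq_len(ncol(x)))
  has_rownames <- !is.null(rownames(x))
  header <- paste(c(if (has_rownames) "row", cols), collapse = "\t")
  body <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(if (has_rownames) rownames(x)[i], fmt_num(x[i, ])), collapse = "\t")
  }, "")
  writeLines(c(provenance_header("matrix", seed), header, body), path)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path, expected_labels = NULL) {
  raw <- readLines(path)
  lines <- raw[!startsWith(raw, "#") & nzchar(raw)]
  if (length(lines) == 0L) stop("no data in ", path, call. = FALSE)
  sep <- if (grepl("\t", lines[[1L]])) "\t" else if (grepl(",", lines[[1L]])) "," else "[[:space:]]+"
  fields <- strsplit(lines, sep)
  first <- fields[[1L]]
  has_header <- anyNA(suppressWarnings(as.numeric(first)))
  col_labels <- NULL
  if (has_header) {
    col_labels <- first
    fields <- fields[-1L]
    if (length(fields) == 0L) stop("matrix in ", path, " has a header but no rows", call. = FALSE)
  }
  # a leading non-numeric field in data rows marks a row-label column
  has_rowlabels <- is.na(suppressWarnings(as.numeric(fields[[1L]][1L])))
  row_labels <- NULL
  if (has_rowlabels) {
    row_labels <- vapply(fields, `[[`, "", 1L)
    fields <- lapply(fields, `[`, -1L)
    if (!is.null(col_labels) && length(col_labels) == length(fields[[1L]]) + 1L) {
      col_labels <- col_labels[-1L]
    }
  }
  widths <- lengths(fields)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1L])[1L]
    stop(
      "ragged matrix in ", path, ": row ", bad, " has ", widths[bad],
      " fields, expected ", widths[1L],
      call. = FALSE
    )
  }
  rows <- lapply(seq_along(fields), function(i) {
    v <- suppressWarnings(as.numeric(fields[[i]]))
    bad <- which(is.na(v) & fields[[i]] != "NA")
    if (length(bad) > 0L) {
      stop(
        "non-numeric value '", fields[[i]][bad[1L]], "' in ", path,
        " at data row ", i, ", column ", bad[1L],
        call. = FALSE
      )
    }
    v
  })
  m <- do.call(rbind, rows)
  if (!is.null(col_labels)) colnames(m) <- col_labels
  if (!is.null(row_labels)) rownames(m) <- row_labels
  if (!is.null(expected_labels) && ncol(m) != length(expected_labels)) {
    stop(
      "matrix in ", path, " has ", ncol(m), " columns but ",
      length(expected_labels), " labels were expected",
      call. = FALSE
    )
  }
  m
}

#' Write / read a BIDS-style events table
#'
#' Events tables carry one row per trial with `onset` (seconds), `duration`
#' (0 for stick events), `trial_type` (switch/repeat), `task` and `cue`
#' columns, plus provenance comments recording the TR and run length so a
#' design round-trips exactly. `read_events()` requires `onset`, `duration`
#' and at least one of `trial_type` / `task`; when `trial_type` is absent
#' the switch/repeat condition is derived from the task sequence (first
#' trial = repeat), and when `task` is absent it is reconstructed from the
#' condition sequence.
#'
#' @param design A `trial_design`.
#' @param path File path.
#' @param tr_s,n_scans Scan parameters; default to the values recorded in
#'   the file header (or TR 2 s and a run covering the last response).
#' @return `read_events()` returns a `trial_design`.
#' @export
write_events <- function(design, path) {
  stopifnot(inherits(design, "trial_design"))
  header <- c(
    provenance_header("events"),
    sprintf("# tr_s=%s", fmt_num(design$tr_s)),
    sprintf("# n_scans=%d", design$n_scans)
  )
  tr <- design$trials
  body <- vapply(seq_len(nrow(tr)), function(i) {
    paste(c(fmt_num(tr$onset_s[i]), "0", tr$condition[i], tr$task[i], tr$cue[i]),
      collapse = "\t"
    )
  }, "")
  writeLines(c(header, "onset\tduration\ttrial_type\ttask\tcue", body), path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path, tr_s = NULL, n_scans = NULL) {
  raw <- readLines(path)
  comments <- raw[startsWith(raw, "#")]
  get_meta <- function(key) {
    hit <- grep(sprintf("^# %s=", key), comments, value = TRUE)
    if (length(hit) == 0L) {
      return(NULL)
    }
    as.numeric(sub(sprintf("^# %s=", key), "", hit[[1L]]))
  }
  df <- utils::read.table(path,
    sep = "\t", header = TRUE, comment.char = "#",
    stringsAsFactors = FALSE
  )
  required <- c("onset", "duration")
  missing_cols <- setdiff(required, names(df))
  if (!any(c("trial_type", "task") %in% names(df))) {
    missing_cols <- c(missing_cols, "trial_type (or task)")
  }
  if (length(missing_cols) > 0L) {
    stop(
      "events table ", path, " is missing required column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  onset <- as.numeric(df$onset)
  if (any(diff(onset) <= 0)) {
    stop("event onsets in ", path, " must be strictly increasing", call. = FALSE)
  }
  n <- nrow(df)
  task <- df$task
  condition <- df$trial_type
  if (is.null(condition)) {
    condition <- c("repeat", ifelse(task[-1L] != task[-n], "switch", "repeat"))
  }
  if (is.null(task)) {
    tasks <- c("shape", "color")
    task <- character(n)
    task[1L] <- tasks[1L]
    for (t in seq_len(n)[-1L]) {
      task[t] <- if (condition[t] == "switch") setdiff(tasks, task[t - 1L]) else task[t - 1L]
    }
  }
  cue <- df$cue %||% rep("full_word", n)
  tr_s <- tr_s %||% get_meta("tr_s") %||% 2
  n_scans <- as.integer(n_scans %||% get_meta("n_scans") %||%
    ceiling((max(onset) + 32) / tr_s))
  structure(
    list(
      trials = data.frame(
        onset_s = onset, task = task, cue = cue, condition = condition,
        stringsAsFactors = FALSE
      ),
      tr_s = tr_s, n_scans = n_scans
    ),
    class = "trial_design"
  )
}

#' Write / read a confounds table
#'
#' Confounds follow the BIDS convention: tab-separated numeric columns named
#' `trans_x`..`rot_z` for the six rigid-body motion parameters plus
#' `white_matter` and `csf` mean signals, one row per scan.
#'
#' @param confounds Data frame or matrix of confound regressors.
#' @param path File path.
#' @return `read_confounds()` returns a data frame.
#' @export
write_confounds <- function(confounds, path) {
  m <- as.matrix(confounds)
  write_matrix(m, path)
  invisible(path)
}

#' @rdname write_confounds
#' @export
read_confounds <- function(path) {
  as.data.frame(read_matrix(path))
}

#' Write / read a subject labels table
#'
#' Two tab-separated columns: `subject_id` and `group`.
#'
#' @param labels Data frame with `subject_id` and `group` columns.
#' @param path File path.
#' @return `read_labels()` returns a data frame.
#' @export
write_labels <- function(labels, path) {
  stopifnot(all(c("subject_id", "group") %in% names(labels)))
  body <- paste(labels$subject_id, labels$group, sep = "\t")
  writeLines(c(provenance_header("labels"), "subject_id\tgroup", body), path)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path,
    sep = "\t", header = TRUE, comment.char = "#",
    stringsAsFactors = FALSE
  )
  missing_cols <- setdiff(c("subject_id", "group"), names(df))
  if (length(missing_cols) > 0L) {
    stop(
      "labels table ", path, " is missing column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  df
}

#' Read an atlas coordinate table
#'
#' Tab-separated table with columns `roi_id`, `x`, `y`, `z` (MNI
#' millimetres) and `network` (community label). Regions listed in
#' `exclude` (e.g. low-signal nodes) are dropped; which regions to exclude
#' is a configuration input, not something the package computes.
#'
#' @param path File path.
#' @param exclude Vector of `roi_id` values to drop.
#' @return Data frame of retained regions.
#' @export
read_atlas <- function(path, exclude = NULL) {
  df <- utils::read.table(path,
    sep = "\t", header = TRUE, comment.char = "#",
    stringsAsFactors = FALSE
  )
  missing_cols <- setdiff(c("roi_id", "x", "y", "z", "network"), names(df))
  if (length(missing_cols) > 0L) {
    stop(
      "atlas table ", path, " is missing column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (!is.null(exclude)) df <- df[!df$roi_id %in% exclude, , drop = FALSE]
  df
}

#' Extract spherical-ROI mean time series from a 4D image array
#'
#' Optional reader utility for volumetric data: averages, for every atlas
#' region, the voxels within `radius_mm` of the region centre at each time
#' point. The image is supplied as a plain 4D array (x, y, z, time), e.g.
#' as returned by `RNifti::readNifti()`, together with its voxel size and
#' the world-space position of voxel (1, 1, 1).
#'
#' @param img 4D numeric array (x, y, z, time).
#' @param atlas Data frame with `roi_id`, `x`, `y`, `z` columns (mm).
#' @param radius_mm Sphere radius in millimetres.
#' @param voxel_size_mm Voxel edge lengths, length-3 vector.
#' @param origin_mm World coordinates of voxel (1, 1, 1), length-3 vector.
#' @return Time x regions matrix of sphere-mean signals.
#' @export
extract_roi_timeseries <- function(img, atlas, radius_mm = 6,
                                   voxel_size_mm = c(3, 3, 3),
                                   origin_mm = c(0, 0, 0)) {
  stopifnot(length(dim(img)) == 4L)
  dims <- dim(img)
  grid <- expand.grid(
    x = seq_len(dims[1]), y = seq_len(dims[2]), z = seq_len(dims[3])
  )
  world <- sweep(sweep(as.matrix(grid) - 1, 2, voxel_size_mm, "*"), 2, origin_mm, "+")
  flat <- matrix(img, prod(dims[1:3]), dims[4])
  out <- vapply(seq_len(nrow(atlas)), function(r) {
    centre <- c(atlas$x[r], atlas$y[r], atlas$z[r])
    d2 <- rowSums(sweep(world, 2, centre)^2)
    inside <- d2 <= radius_mm^2
    if (!any(inside)) {
      stop("no voxels within ", radius_mm, " mm of region ", atlas$roi_id[r],
        call. = FALSE
      )
    }
    colMeans(flat[inside, , drop = FALSE])
  }, numeric(dims[4]))
  colnames(out) <- as.character(atlas$roi_id)
  out
}
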