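#' Text-format dialects for skeleton files
#'
#' The canonical on-disk format is a delimited text file with one row per
#' (frame, joint) pair and columns `frame, joint, x, y, z`, preceded by
#' `#key=value` comment lines carrying the subject id, sequence id and frame
#' rate. Public Kinect gait collections ship in assorted ad hoc text layouts,
#' so a *dialect* descriptor adapts the reader: the delimiter, the column
#' order, whether a `frame` and/or `joint` column is present (if absent, rows
#' are assumed to cycle through the schema's joints, `Nb` consecutive rows per
#' frame), and an optional joint-name vector mapping the file's joint order
#' onto the canonical schema.
#'
#' @param delim Field delimiter (default `","`).
#' @param columns Character vector naming the file's columns in order; must
#'   contain `x`, `y`, `z`, and may contain `frame` and `joint`.
#' @param joint_names Optional character vector: the file's joint ordering by
#'   name, mapped onto the schema at read time. When `NULL`, joint indices or
#'   row order are taken to already follow the schema.
#' @param decimal Decimal mark (default `"."`).
#' @return A `skeleton_dialect` list.
#' @seealso [read_skeleton_csv()], [write_skeleton_csv()]
#' @export
skeleton_dialect <- function(delim = ",", columns = c("frame", "joint", "x", "y", "z"),
                             joint_names = NULL, decimal = ".") {
  columns <- as.character(columns)
  if (!all(c("x", "y", "z") %in% columns)) {
    abort("A dialect must provide x, y and z columns.")
  }
  structure(list(delim = delim, columns = columns,
                 joint_names = joint_names, decimal = decimal),
            class = "skeleton_dialect")
}

#' @rdname skeleton_dialect
#' @param path Path to a YAML file with any of the fields of
#'   [skeleton_dialect()].
#' @export
read_dialect <- function(path) {
  cfg <- yaml::read_yaml(path)
  # bare y/n in YAML are booleans; in a column list they mean the y/n columns
  fix_yn <- function(v) {
    vapply(v, function(ci) {
      if (isTRUE(ci)) "y" else if (isFALSE(ci)) "n" else as.character(ci)
    }, character(1))
  }
  for (f in c("columns", "joint_names")) {
    if (!is.null(cfg[[f]])) cfg[[f]] <- fix_yn(cfg[[f]])
  }
  do.call(skeleton_dialect, cfg[intersect(names(cfg),
                                          names(formals(skeleton_dialect)))])
}

#' Read and write skeleton sequences
#'
#' `write_skeleton_csv()` emits the canonical format; reading it back yields a
#' sequence identical to the one written (coordinates are serialized with 17
#' significant digits, enough to round-trip doubles bit-exactly).
#' `read_skeleton_csv()` parses any dialect and validates the result against
#' the schema, reporting the offending line number on malformed input.
#'
#' @param path File path.
#' @param dialect A [skeleton_dialect]; the default is the canonical format.
#' @param schema Target [joint_schema].
#' @param subject_id,sequence_id,fps Metadata; when `NULL` they are taken from
#'   `#key=value` header lines if present, else derived from the file name.
#' @return `read_skeleton_csv()` a [skeleton_sequence]; `write_skeleton_csv()`
#'   the path, invisibly.
#' @examples
#' seq <- synthesize_sequence(sample_population(2, seed = 1)[1, ],
#'                            duration = 1, seed = 1)
#' f <- tempfile(fileext = ".csv")
#' write_skeleton_csv(seq, f)
#' identical(as.data.frame(read_skeleton_csv(f)), as.data.frame(seq))
#' @export
read_skeleton_csv <- function(path, dialect = skeleton_dialect(),
                              schema = kinect20_schema(),
                              subject_id = NULL, sequence_id = NULL, fps = NULL) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  lines <- readLines(path, warn = FALSE)
  meta <- list()
  hdr <- grepl("^#", lines)
  for (h in lines[hdr]) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z_]+)\\s*=\\s*(.*)$", h))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- m[3]
  }
  keep <- which(!hdr & nzchar(trimws(lines)))
  body <- lines[keep]
  if (length(body) && identical(strsplit(body[1], dialect$delim, fixed = TRUE)[[1]],
                                dialect$columns)) {
    body <- body[-1]
    keep <- keep[-1]
  }
  parts <- strsplit(body, dialect$delim, fixed = TRUE)
  ncol_exp <- length(dialect$columns)
  lens <- lengths(parts)
  if (any(lens != ncol_exp)) {
    bad <- which(lens != ncol_exp)[1L]
    abort(sprintf("Parse error at line %d of %s: expected %d fields, found %d.",
                  keep[bad], path, ncol_exp, lens[bad]))
  }
  n <- length(parts)
  if (n > 0L) {
    fields <- matrix(unlist(parts, use.names = FALSE), nrow = n, byrow = TRUE)
    colnames(fields) <- dialect$columns
    if (!identical(dialect$decimal, ".")) {
      fields[, c("x", "y", "z")] <- gsub(dialect$decimal, ".",
                                         fields[, c("x", "y", "z")], fixed = TRUE)
    }
  }
  num <- function(col) {
    v <- suppressWarnings(as.numeric(fields[, col]))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      abort(sprintf("Parse error at line %d of %s: non-numeric or non-finite %s value '%s'.",
                    keep[bad[1]], path, col, fields[bad[1], col]))
    }
    v
  }
  nb <- schema$n_joints
  if (n == 0L) {
    dat <- tibble(frame = integer(), joint = integer(),
                  x = double(), y = double(), z = double())
  } else {
    x <- num("x"); y <- num("y"); z <- num("z")
    if ("joint" %in% dialect$columns) {
      jraw <- fields[, "joint"]
      if (!is.null(dialect$joint_names) || any(is.na(suppressWarnings(as.integer(jraw))))) {
        jnames <- dialect$joint_names %||% schema$names
        joint <- match(jraw, jnames)
        if (anyNA(joint)) {
          bad <- which(is.na(joint))[1L]
          abort(sprintf("Parse error at line %d of %s: unknown joint '%s'.",
                        keep[bad], path, jraw[bad]))
        }
        if (!is.null(dialect$joint_names)) {
          joint <- match(jnames, schema$names)[joint]
          if (anyNA(joint)) abort("Dialect joint_names do not all map onto the schema.")
        }
      } else {
        joint <- as.integer(jraw)
      }
    } else {
      if (n %% nb != 0L) {
        abort(sprintf("File %s has %d data rows, not a multiple of Nb = %d.",
                      path, n, nb))
      }
      joint <- rep(seq_len(nb), times = n %/% nb)
      if (!is.null(dialect$joint_names)) {
        joint <- match(dialect$joint_names, schema$names)[joint]
      }
    }
    if ("frame" %in% dialect$columns) {
      frame <- suppressWarnings(as.integer(fields[, "frame"]))
      if (anyNA(frame)) {
        bad <- which(is.na(frame))[1L]
        abort(sprintf("Parse error at line %d of %s: bad frame index '%s'.",
                      keep[bad], path, fields[bad, "frame"]))
      }
    } else {
      frame <- rep(seq_len(n %/% nb) - 1L, each = nb)
    }
    dat <- tibble(frame = frame, joint = joint, x = x, y = y, z = z)
  }
  stem <- sub("\\.[^.]*$", "", basename(path))
  skeleton_sequence(
    dat,
    subject_id = subject_id %||% meta$subject_id %||% stem,
    sequence_id = sequence_id %||% meta$sequence_id %||% stem,
    fps = as.numeric(fps %||% meta$fps %||% 30),
    schema = schema
  )
}

#' @rdname read_skeleton_csv
#' @param seq A [skeleton_sequence] to serialize.
#' @export
write_skeleton_csv <- function(seq, path) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  sch <- attr(seq, "schema")
  hdr <- c(
    sprintf("#subject_id=%s", attr(seq, "subject_id")),
    sprintf("#sequence_id=%s", attr(seq, "sequence_id")),
    sprintf("#fps=%s", format(attr(seq, "fps"), digits = 17)),
    "frame,joint,x,y,z"
  )
  rows <- sprintf("%d,%s,%s,%s,%s",
                  seq$frame, sch$names[seq$joint],
                  formatC(seq$x, format = "g", digits = 17),
                  formatC(seq$y, format = "g", digits = 17),
                  formatC(seq$z, format = "g", digits = 17))
  ok <- tryCatch({
    writeLines(c(hdr, rows), path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) abort(paste0("Cannot write ", path, ": ", conditionMessage(ok)))
  invisible(path)
}
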