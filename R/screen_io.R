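# Tabular IO for colony tables, screen tables and hit tables.
#
# All files are TSV with '#'-prefixed comment lines, a mandatory header and
# "NA" as the sole missing-value token. Numeric columns are written with 15
# significant digits so that write -> read round-trips to better than 1e-12.

CONDITION_LEVELS <- c("experimental", "control_a", "control_b", "gfp_free")

#' Reserved strain-identifier prefix for GFP-free reference colonies
#'
#' GFP-free control colonies share physical plates with every condition, so
#' they are identified by a reserved, case-sensitive strain-id prefix rather
#' than by the `condition` column (which records the plate copy they sit on).
#' @return The reserved prefix, a character scalar.
#' @export
gfp_free_prefix <- function() "gfp_free"

#' Is a strain identifier a GFP-free reference?
#' @param strain_id character vector of strain identifiers.
#' @return logical vector.
#' @export
is_gfp_free <- function(strain_id) {
  startsWith(as.character(strain_id), gfp_free_prefix())
}

#' Plate geometry
#'
#' Dimensions of the colony grid on one plate, e.g. 16 x 24 for 384-format
#' or 32 x 48 for 1536-format arrays. Rows and columns are 1-based integers.
#'
#' @param n_rows,n_cols positive integers.
#' @return An object of class `plate_geometry`.
#' @export
plate_geometry <- function(n_rows, n_cols) {
  stopifnot(length(n_rows) == 1, length(n_cols) == 1)
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1 || n_cols < 1)
    stop("plate geometry must have n_rows >= 1 and n_cols >= 1")
  structure(list(n_rows = n_rows, n_cols = n_cols), class = "plate_geometry")
}

#' @export
print.plate_geometry <- function(x, ...) {
  cat(sprintf("<plate_geometry %d x %d>\n", x$n_rows, x$n_cols))
  invisible(x)
}

#' Parse a "16x24"-style geometry string
#' @param text e.g. "16x24".
#' @return A `plate_geometry`.
#' @export
parse_geometry <- function(text) {
  m <- regmatches(text, regexec("^([0-9]+)x([0-9]+)$", text))[[1]]
  if (length(m) != 3) stop("geometry must look like '16x24', got: ", text)
  plate_geometry(as.integer(m[2]), as.integer(m[3]))
}

COLONY_COLUMNS <- c("plate_id", "row", "col", "strain_id", "condition",
                    "replicate", "size")

num_fmt <- function(x, digits = 15) {
  out <- ifelse(is.na(x), "NA", sprintf(paste0("%.", digits, "g"), x))
  out
}

# Read a commented TSV: returns list(comments, header, rows, line_numbers)
read_tsv_lines <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path)
  is_comment <- startsWith(lines, "#")
  body_idx <- which(!is_comment & nzchar(lines))
  if (length(body_idx) == 0) stop("file has no header row: ", path)
  header <- strsplit(lines[body_idx[1]], "\t", fixed = TRUE)[[1]]
  data_idx <- body_idx[-1]
  rows <- strsplit(lines[data_idx], "\t", fixed = TRUE)
  list(comments = lines[is_comment], header = header,
       rows = rows, line_numbers = data_idx)
}

check_header <- function(header, expected, path) {
  missing <- setdiff(expected, header)
  if (length(missing) > 0)
    stop(sprintf("malformed header in %s: missing column(s) %s",
                 path, paste(missing, collapse = ", ")))
  extra <- setdiff(header, expected)
  if (length(extra) > 0)
    stop(sprintf("malformed header in %s: unexpected column(s) %s",
                 path, paste(extra, collapse = ", ")))
}

field <- function(rows, header, name) {
  vapply(rows, function(r) r[match(name, header)], character(1))
}

as_num <- function(x) {
  out <- suppressWarnings(as.numeric(ifelse(x == "NA", NA, x)))
  out
}

#' Validate a colony observation table
#'
#' Checks the table against the colony-observation contract: 1-based grid
#' coordinates inside the declared geometry, non-negative sizes (size 0
#' encodes a dead colony, never missingness), known condition labels, and
#' uniqueness of (plate_id, row, col) within each condition + replicate.
#'
#' @param df data.frame with columns plate_id, row, col, strain_id,
#'   condition, replicate, size.
#' @param geometry a [plate_geometry()].
#' @param lines optional integer vector of source line numbers used in error
#'   messages.
#' @return The validated data.frame, invisibly classed `colony_table`.
#' @export
validate_colony_table <- function(df, geometry, lines = NULL) {
  if (is.null(lines)) lines <- seq_len(nrow(df))
  where <- function(i) sprintf("line %d", lines[i])
  bad <- which(is.na(df$row) | is.na(df$col) | df$row < 1 | df$col < 1)
  if (length(bad) > 0)
    stop(sprintf("invalid grid coordinate (%s): row/col must be >= 1",
                 where(bad[1])))
  bad <- which(df$row > geometry$n_rows | df$col > geometry$n_cols)
  if (length(bad) > 0)
    stop(sprintf("coordinate outside %dx%d plate geometry (%s)",
                 geometry$n_rows, geometry$n_cols, where(bad[1])))
  bad <- which(!(df$condition %in% CONDITION_LEVELS))
  if (length(bad) > 0)
    stop(sprintf("unknown condition '%s' (%s)", df$condition[bad[1]],
                 where(bad[1])))
  bad <- which(is.na(df$replicate) | df$replicate < 1)
  if (length(bad) > 0)
    stop(sprintf("replicate must be a positive integer (%s)", where(bad[1])))
  bad <- which(is.na(df$size) | df$size < 0)
  if (length(bad) > 0)
    stop(sprintf("size must be a non-negative number (%s)", where(bad[1])))
  key <- paste(df$plate_id, df$row, df$col, df$condition, df$replicate,
               sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0)
    stop(sprintf("duplicate position: plate %s row %d col %d (%s)",
                 df$plate_id[dup[1]], df$row[dup[1]], df$col[dup[1]],
                 where(dup[1])))
  class(df) <- c("colony_table", "data.frame")
  invisible(df)
}

#' Read a colony-size table
#'
#' @param path TSV file with columns plate_id, row, col, strain_id,
#'   condition, replicate, size. Lines starting with '#' are comments.
#' @param geometry a [plate_geometry()] the coordinates must respect.
#' @return A data.frame of validated colony observations.
#' @export
read_colony_table <- function(path, geometry) {
  parsed <- read_tsv_lines(path)
  check_header(parsed$header, COLONY_COLUMNS, path)
  df <- data.frame(
    plate_id  = field(parsed$rows, parsed$header, "plate_id"),
    row       = as.integer(as_num(field(parsed$rows, parsed$header, "row"))),
    col       = as.integer(as_num(field(parsed$rows, parsed$header, "col"))),
    strain_id = field(parsed$rows, parsed$header, "strain_id"),
    condition = field(parsed$rows, parsed$header, "condition"),
    replicate = as.integer(as_num(field(parsed$rows, parsed$header,
                                        "replicate"))),
    size      = as_num(field(parsed$rows, parsed$header, "size")),
    stringsAsFactors = FALSE
  )
  validate_colony_table(df, geometry, lines = parsed$line_numbers)
  df
}

#' Write a colony-size table
#' @param df colony observations (see [read_colony_table()] for columns).
#' @param path output TSV path.
#' @param comments optional character vector written as '#' lines.
#' @return `path`, invisibly.
#' @export
write_colony_table <- function(df, path, comments = character(0)) {
  lines <- c(if (length(comments)) paste0("# ", comments),
             paste(COLONY_COLUMNS, collapse = "\t"),
             paste(df$plate_id, df$row, df$col, df$strain_id, df$condition,
                   df$replicate, num_fmt(df$size), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a screen table
#'
#' Per-strain results of one screen: raw and spatially smoothed log growth
#' ratios (LGRs) and Z-scores. Strain identifiers must be unique (duplicate
#' library copies are aggregated beforehand).
#'
#' @param screen_name character scalar.
#' @param data data.frame with columns strain_id, lgr_raw, lgr_smoothed,
#'   z_score (the latter two may be NA before those stages run).
#' @param n_replicates positive integer, replicates in the underlying screen.
#' @param provenance free-text metadata.
#' @return An object of class `screen_table`.
#' @export
screen_table <- function(screen_name, data, n_replicates = NA_integer_,
                         provenance = "") {
  required <- c("strain_id", "lgr_raw", "lgr_smoothed", "z_score")
  missing <- setdiff(required, names(data))
  if (length(missing))
    stop("screen table data missing column(s): ",
         paste(missing, collapse = ", "))
  dup <- data$strain_id[duplicated(data$strain_id)]
  if (length(dup))
    stop("duplicate strain_id in screen table: ", dup[1])
  z <- data$z_score
  if (any(!is.na(z)) && all(!is.na(z)) && length(z) >= 2) {
    if (abs(mean(z)) > 1e-9 || abs(stats::sd(z) - 1) > 1e-9)
      stop("z_score column must have mean 0 and sd 1 (within 1e-9)")
  }
  structure(list(screen_name = screen_name,
                 data = data[required],
                 n_replicates = n_replicates,
                 provenance = provenance),
            class = "screen_table")
}

#' @export
print.screen_table <- function(x, ...) {
  cat(sprintf("<screen_table '%s': %d strains, %s replicates>\n",
              x$screen_name, nrow(x$data),
              ifelse(is.na(x$n_replicates), "?", x$n_replicates)))
  invisible(x)
}

#' Write / read a screen table
#'
#' Metadata travel in '#key: value' comment lines; numeric columns use 15
#' significant digits so the round-trip is the identity to well below 1e-12.
#'
#' @param screen a [screen_table()].
#' @param path TSV path.
#' @param digits significant digits for numeric columns.
#' @return `path` invisibly (write); a `screen_table` (read).
#' @export
write_screen_table <- function(screen, path, digits = 15) {
  d <- screen$data
  lines <- c(sprintf("#screen_name: %s", screen$screen_name),
             sprintf("#n_replicates: %s",
                     ifelse(is.na(screen$n_replicates), "NA",
                            screen$n_replicates)),
             sprintf("#provenance: %s", screen$provenance),
             "strain_id\tlgr_raw\tlgr_smoothed\tz_score")
  if (nrow(d) > 0)
    lines <- c(lines,
               paste(d$strain_id, num_fmt(d$lgr_raw, digits),
                     num_fmt(d$lgr_smoothed, digits),
                     num_fmt(d$z_score, digits), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_screen_table
#' @export
read_screen_table <- function(path) {
  parsed <- read_tsv_lines(path)
  check_header(parsed$header,
               c("strain_id", "lgr_raw", "lgr_smoothed", "z_score"), path)
  meta <- function(key, default = "") {
    hit <- grep(paste0("^#", key, ": ?"), parsed$comments, value = TRUE)
    if (length(hit) == 0) return(default)
    sub(paste0("^#", key, ": ?"), "", hit[1])
  }
  d <- data.frame(
    strain_id    = field(parsed$rows, parsed$header, "strain_id"),
    lgr_raw      = as_num(field(parsed$rows, parsed$header, "lgr_raw")),
    lgr_smoothed = as_num(field(parsed$rows, parsed$header, "lgr_smoothed")),
    z_score      = as_num(field(parsed$rows, parsed$header, "z_score")),
    stringsAsFactors = FALSE
  )
  if (length(parsed$rows) == 0)
    d <- d[0, , drop = FALSE]
  nrep <- meta("n_replicates", "NA")
  screen_table(meta("screen_name"),
               d,
               n_replicates = if (nrep == "NA") NA_integer_
                              else as.integer(nrep),
               provenance = meta("provenance"))
}

HIT_COLUMNS <- c("strain_id", "lgr", "z_score", "q", "pv", "hit_z", "hit_q",
                 "enhancer", "flags")

#' Write / read a hit table
#' @param hits data.frame with columns strain_id, lgr, z_score, q, pv,
#'   hit_z, hit_q, enhancer, flags.
#' @param path TSV path.
#' @param comments optional '#' comment lines.
#' @return `path` invisibly (write); a data.frame (read).
#' @export
write_hit_table <- function(hits, path, comments = character(0)) {
  logical_fmt <- function(x) ifelse(is.na(x), "NA", ifelse(x, "TRUE", "FALSE"))
  lines <- c(if (length(comments)) paste0("# ", comments),
             paste(HIT_COLUMNS, collapse = "\t"),
             if (nrow(hits) > 0)
               paste(hits$strain_id, num_fmt(hits$lgr), num_fmt(hits$z_score),
                     num_fmt(hits$q), num_fmt(hits$pv),
                     logical_fmt(hits$hit_z), logical_fmt(hits$hit_q),
                     logical_fmt(hits$enhancer), hits$flags, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_hit_table
#' @export
read_hit_table <- function(path) {
  parsed <- read_tsv_lines(path)
  check_header(parsed$header, HIT_COLUMNS, path)
  as_lgl <- function(x) ifelse(x == "NA", NA, x == "TRUE")
  df <- data.frame(
    strain_id = field(parsed$rows, parsed$header, "strain_id"),
    lgr       = as_num(field(parsed$rows, parsed$header, "lgr")),
    z_score   = as_num(field(parsed$rows, parsed$header, "z_score")),
    q         = as_num(field(parsed$rows, parsed$header, "q")),
    pv        = as_num(field(parsed$rows, parsed$header, "pv")),
    hit_z     = as_lgl(field(parsed$rows, parsed$header, "hit_z")),
    hit_q     = as_lgl(field(parsed$rows, parsed$header, "hit_q")),
    enhancer  = as_lgl(field(parsed$rows, parsed$header, "enhancer")),
    # trailing empty field: strsplit drops it, recover as ""
    flags     = ifelse(is.na(field(parsed$rows, parsed$header, "flags")),
                       "", field(parsed$rows, parsed$header, "flags")),
    stringsAsFactors = FALSE
  )
  dup <- df$strain_id[duplicated(df$strain_id)]
  if (length(dup)) stop("duplicate strain_id in hit table: ", dup[1])
  df
}
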