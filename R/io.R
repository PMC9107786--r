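#' Read a community phenology table from CSV
#'
#' Two layouts are supported. *Wide*: first column is time, one further
#' column per species (`time,<sp1>,<sp2>,...`). *Long*: three columns
#' `time,species,value`, one row per observation. Either way the time
#' grid must be evenly spaced and all values nonnegative. Missing cells
#' (empty fields in wide layout, absent rows in long layout) are treated
#' as sampling gaps: they are stored as 0 and flagged in the `gaps`
#' element, so that wavelet smoothing can interpolate across them.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @param layout `"wide"` (default) or `"long"`.
#' @param stage Stage flag attached to the result, `"raw"` by default;
#'   use `"smoothed"` when the file already holds continuous curves.
#' @return A [phenology_community()].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("time,sp1,sp2", "0,1,0", "1,2,1", "2,1,2", "3,0,1"), f)
#' read_community(f)
#' @export
read_community <- function(path, layout = c("wide", "long"),
                           stage = c("raw", "smoothed")) {
  layout <- match.arg(layout)
  stage <- match.arg(stage)
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0 || ncol(df) < 2) {
    stop("'", path, "' does not look like a community table (need a header ",
         "row and at least two columns)", call. = FALSE)
  }
  if (layout == "wide") {
    read_community_wide(df, path, stage)
  } else {
    read_community_long(df, path, stage)
  }
}

read_community_wide <- function(df, path, stage) {
  times <- parse_numeric_column(df[[1]], names(df)[1], path)
  vals <- df[-1]
  for (j in seq_along(vals)) {
    vals[[j]] <- parse_numeric_column(vals[[j]], names(vals)[j], path,
                                      allow_na = TRUE)
  }
  m <- as.matrix(vals)
  gaps <- is.na(m)
  m[gaps] <- 0
  comm <- phenology_community(times, m, species = names(vals), stage = stage,
                              gaps = if (any(gaps)) gaps)
  comm
}

read_community_long <- function(df, path, stage) {
  if (ncol(df) != 3) {
    stop("long layout requires exactly 3 columns (time, species, value); '",
         path, "' has ", ncol(df), call. = FALSE)
  }
  t_raw <- parse_numeric_column(df[[1]], names(df)[1], path)
  sp <- as.character(df[[2]])
  v <- parse_numeric_column(df[[3]], names(df)[3], path, allow_na = TRUE)
  times <- sort(unique(t_raw))
  species <- unique(sp)             # order of first appearance
  key <- paste(t_raw, sp, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    d <- strsplit(d, "\r", fixed = TRUE)[[1]]
    stop("duplicate (time, species) pair in '", path, "': time ", d[1],
         ", species '", d[2], "'", call. = FALSE)
  }
  m <- matrix(NA_real_, length(times), length(species),
              dimnames = list(NULL, species))
  m[cbind(match(t_raw, times), match(sp, species))] <- v
  gaps <- is.na(m)
  m[gaps] <- 0
  phenology_community(times, m, species = species, stage = stage,
                      gaps = if (any(gaps)) gaps)
}

parse_numeric_column <- function(x, col, path, allow_na = FALSE) {
  if (is.numeric(x)) return(as.numeric(x))
  was_blank <- is.na(x) | trimws(as.character(x)) == ""
  out <- suppressWarnings(as.numeric(x))
  bad <- is.na(out) & !was_blank
  if (any(bad)) {
    row <- which(bad)[1]
    stop("non-numeric value '", x[row], "' in column '", col, "', data row ",
         row, " of '", path, "'", call. = FALSE)
  }
  if (!allow_na && any(was_blank)) {
    stop("missing value in column '", col, "', data row ",
         which(was_blank)[1], " of '", path, "'", call. = FALSE)
  }
  out
}

#' Write a community or distance matrix to CSV
#'
#' Writes either a [phenology_community()] (wide layout, `time` first
#' column) or a square pairwise-distance matrix (species labels on both
#' axes). Values are written with 17 significant digits so a write/read
#' round trip reproduces them bitwise.
#'
#' @param m A `phenology_community` or a square numeric matrix with
#'   species labels as dimnames (e.g. from [distance_matrix()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  if (inherits(m, "phenology_community")) {
    if (length(m$species) == 0) {
      stop("refusing to write an empty community (no species)", call. = FALSE)
    }
    tab <- cbind(fmt_num(m$times),
                 apply(m$intensity, 2, fmt_num))
    header <- c("time", m$species)
  } else if (is.matrix(m)) {
    if (nrow(m) != ncol(m)) {
      stop("distance matrix must be square", call. = FALSE)
    }
    if (nrow(m) == 0) {
      stop("refusing to write an empty matrix", call. = FALSE)
    }
    labels <- rownames(m)
    if (is.null(labels)) labels <- paste0("sp", seq_len(nrow(m)))
    tab <- cbind(labels, apply(m, 2, fmt_num))
    header <- c("species", labels)
  } else {
    stop("'m' must be a phenology_community or a square matrix", call. = FALSE)
  }
  con <- tryCatch(file(path, open = "wt", encoding = "UTF-8"),
                  error = function(e) {
                    stop("cannot open '", path, "' for writing: ",
                         conditionMessage(e), call. = FALSE)
                  })
  on.exit(close(con))
  writeLines(paste(csv_quote(header), collapse = ","), con)
  writeLines(apply(tab, 1, function(r) paste(csv_quote(r), collapse = ",")),
             con)
  invisible(path)
}

# shortest decimal form that round-trips a double exactly
fmt_num <- function(x) {
  vapply(x, function(v) {
    for (d in c(15L, 16L, 17L)) {
      s <- sprintf("%.*g", d, v)
      if (as.numeric(s) == v) return(s)
    }
    s
  }, character(1))
}

csv_quote <- function(x) {
  needs <- grepl('[",\n]', x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

#' Read a square labelled distance matrix from CSV
#'
#' Inverse of [write_matrix()] for pairwise-distance matrices.
#'
#' @param path Path to a CSV written by [write_matrix()].
#' @return A square numeric matrix with species labels as dimnames.
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- as.character(df[[1]])
  m <- as.matrix(df[-1])
  storage.mode(m) <- "double"
  dimnames(m) <- list(labels, names(df)[-1])
  m
}
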