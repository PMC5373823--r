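#' Construct a localization table
#'
#' A localization table is the point-pattern record of single-molecule
#' detections: one row per localized fluorophore emission event, with
#' coordinates in nanometers, the camera frame in which the event was
#' detected, a channel label, and (optionally) the localization precision.
#' It is the common currency of the whole package: synthetic generators
#' produce it, the correlation, density and tracking analyses consume it.
#'
#' Tables are kept in canonical order, sorted by `(channel, frame)`; sorting
#' is idempotent so repeated construction is a no-op.
#'
#' @param x,y numeric, coordinates in nm. Must be finite.
#' @param frame integer vector of frame indices, non-negative.
#' @param channel channel labels (character or factor); recycled if scalar.
#' @param sigma_nm optional per-localization precision in nm.
#' @param cell_id optional cell label.
#' @param molecule_id optional ground-truth molecule index (synthetic data
#'   only; retained for test oracles, not written by [write_localizations()]).
#' @return a `data.frame` of class `loc_table` with columns `x_nm`, `y_nm`,
#'   `frame`, `channel` and optionally `sigma_nm`, `cell_id`, `molecule_id`.
#' @export
loc_table <- function(x, y, frame = 0L, channel = "ch1", sigma_nm = NULL,
                      cell_id = NULL, molecule_id = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n > 0 && (!all(is.finite(x)) || !all(is.finite(y))))
    stop("localization coordinates must be finite")
  frame <- as.integer(rep_len(frame, n))
  if (n > 0 && any(frame < 0L)) stop("frame indices must be non-negative")
  channel <- as.character(rep_len(channel, n))
  df <- data.frame(x_nm = as.numeric(x), y_nm = as.numeric(y),
                   frame = frame, channel = channel,
                   stringsAsFactors = FALSE)
  if (!is.null(sigma_nm)) df$sigma_nm <- as.numeric(rep_len(sigma_nm, n))
  if (!is.null(cell_id)) df$cell_id <- rep_len(cell_id, n)
  if (!is.null(molecule_id)) df$molecule_id <- rep_len(as.integer(molecule_id), n)
  df <- df[order(df$channel, df$frame), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("loc_table", "data.frame")
  df
}

#' @export
print.loc_table <- function(x, ...) {
  cat(sprintf("<loc_table> %d localizations, %d channel(s): %s\n",
              nrow(x), length(unique(x$channel)),
              paste(unique(x$channel), collapse = ", ")))
  if (nrow(x) > 0)
    cat(sprintf("  frames %d..%d; x [%.0f, %.0f] nm; y [%.0f, %.0f] nm\n",
                min(x$frame), max(x$frame), min(x$x_nm), max(x$x_nm),
                min(x$y_nm), max(x$y_nm)))
  invisible(x)
}

#' Extract one channel of a localization table
#' @param locs a [loc_table()].
#' @param channel channel label to keep.
#' @return a `loc_table` restricted to `channel`.
#' @export
split_channel <- function(locs, channel) {
  stopifnot(inherits(locs, "loc_table"))
  out <- locs[locs$channel == channel, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(locs)
  out
}

#' Read a localization table from CSV
#'
#' Two dialects are supported. `"native"` is the package's own format with
#' columns `x_nm`, `y_nm`, `frame`, `channel` and optional `sigma_nm`.
#' `"thunderstorm"` accepts ThunderSTORM-style exports whose coordinate
#' headers carry units in square brackets (`"x [nm]"` or `"x [um]"`);
#' micrometer columns are converted to nm. A missing channel column is
#' filled with `default_channel`.
#'
#' @param path CSV file path.
#' @param dialect `"native"` or `"thunderstorm"`.
#' @param default_channel channel label used when the file has none.
#' @return a [loc_table()].
#' @export
read_localizations <- function(path, dialect = c("native", "thunderstorm"),
                               default_channel = "ch1") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) == 0) {
    warning("empty localization file: ", path)
    return(loc_table(numeric(0), numeric(0)))
  }
  if (dialect == "native") {
    need <- c("x_nm", "y_nm", "frame", "channel")
    miss <- setdiff(need, names(raw))
    if (length(miss))
      stop("native localization CSV is missing columns: ",
           paste(miss, collapse = ", "))
    x <- raw$x_nm; y <- raw$y_nm
    sig <- if ("sigma_nm" %in% names(raw)) raw$sigma_nm else NULL
    ch <- raw$channel
    fr <- raw$frame
  } else {
    find_coord <- function(letter) {
      hit <- grep(paste0("^", letter, " ?\\[(nm|um)\\]$"), names(raw))
      if (!length(hit) && letter %in% names(raw)) hit <- match(letter, names(raw))
      if (!length(hit))
        stop("ThunderSTORM CSV is missing a '", letter, "' coordinate column")
      hit[1]
    }
    ix <- find_coord("x"); iy <- find_coord("y")
    scale_of <- function(i) if (grepl("\\[um\\]", names(raw)[i])) 1000 else 1
    x <- raw[[ix]] * scale_of(ix)
    y <- raw[[iy]] * scale_of(iy)
    fr <- if ("frame" %in% names(raw)) raw$frame else 0L
    ch <- if ("channel" %in% names(raw)) raw$channel else default_channel
    isig <- grep("^(sigma|uncertainty) ?\\[(nm|um)\\]$", names(raw))
    sig <- if (length(isig)) raw[[isig[1]]] * scale_of(isig[1]) else NULL
  }
  bad <- !is.finite(x) | !is.finite(y) | !is.finite(fr) | fr < 0
  if (any(bad)) {
    warning(sum(bad), " malformed row(s) dropped from ", path)
    x <- x[!bad]; y <- y[!bad]; fr <- fr[!bad]
    ch <- rep_len(ch, length(bad))[!bad]
    if (!is.null(sig)) sig <- rep_len(sig, length(bad))[!bad]
  }
  if (any(fr != floor(fr))) stop("frame column must contain integers")
  loc_table(x, y, fr, ch, sigma_nm = sig)
}

#' Write a localization table to CSV (native dialect)
#' @param locs a [loc_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(locs, path) {
  stopifnot(inherits(locs, "loc_table"))
  keep <- intersect(c("x_nm", "y_nm", "frame", "channel", "sigma_nm", "cell_id"),
                    names(locs))
  utils::write.csv(as.data.frame(locs)[, keep, drop = FALSE], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
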