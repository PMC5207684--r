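#' Read a gaze CSV into a panel
#'
#' Expected dialect: columns `time_ms,subject,x_px,y_px`, one row per sample
#' per subject; missing samples encoded as empty fields (or absent rows).
#'
#' @param path file path.
#' @return a [gaze_panel].
#' @export
read_gaze_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_ms", "subject", "x_px", "y_px")
  if (!all(need %in% names(df)))
    stop("gaze CSV must have columns time_ms,subject,x_px,y_px")
  times <- sort(unique(df$time_ms))
  subjects <- unique(df$subject)
  x <- matrix(NA_real_, length(times), length(subjects))
  y <- x
  ti <- match(df$time_ms, times)
  si <- match(df$subject, subjects)
  x[cbind(ti, si)] <- suppressWarnings(as.numeric(df$x_px))
  y[cbind(ti, si)] <- suppressWarnings(as.numeric(df$y_px))
  gaze_panel(times, x, y, subjects = subjects)
}

#' Write a panel in the gaze CSV dialect
#'
#' @param panel a [gaze_panel].
#' @param path output path; missing samples become empty fields.
#' @export
write_gaze_csv <- function(panel, path) {
  stopifnot(inherits(panel, "gaze_panel"))
  n_t <- nrow(panel$x); n_s <- ncol(panel$x)
  df <- data.frame(
    time_ms = rep(panel$times, n_s),
    subject = rep(panel$subjects, each = n_t),
    x_px = as.vector(panel$x),
    y_px = as.vector(panel$y)
  )
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read per-subject ratings (`subject,video,rating`)
#' @param path file path.
#' @return data.frame.
#' @export
read_ratings_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("subject", "video", "rating") %in% names(df)))
    stop("ratings CSV must have columns subject,video,rating")
  df
}

#' Read population ratings (`video,population_rating`)
#' @param path file path.
#' @return data.frame.
#' @export
read_population_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("video", "population_rating") %in% names(df)))
    stop("population CSV must have columns video,population_rating")
  df
}

#' Serialise a fitted model to plain-text files
#'
#' Writes the coupling matrix as a tab-separated square table with a header
#' of subject ids, and the fields as a `subject,h_x,h_y` table.
#'
#' @param model an [xy_model].
#' @param j_path,h_path output paths (`h_path` optional).
#' @export
write_xy_model <- function(model, j_path, h_path = NULL) {
  stopifnot(inherits(model, "xy_model"))
  J <- model$J
  dimnames(J) <- list(model$subjects, model$subjects)
  utils::write.table(J, j_path, sep = "\t", quote = FALSE, col.names = NA)
  if (!is.null(h_path)) {
    hdf <- data.frame(subject = model$subjects,
                      h_x = model$h[, 1], h_y = model$h[, 2])
    utils::write.table(hdf, h_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(j_path)
}

#' Read a serialised model
#' @param j_path coupling matrix path (as written by [write_xy_model]).
#' @param h_path optional fields table path.
#' @return an [xy_model].
#' @export
read_xy_model <- function(j_path, h_path = NULL) {
  J <- as.matrix(utils::read.table(j_path, sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE))
  h <- NULL
  if (!is.null(h_path)) {
    hdf <- utils::read.table(h_path, sep = "\t", header = TRUE)
    h <- as.matrix(hdf[, c("h_x", "h_y")])
  }
  xy_model(J, h, subjects = rownames(J))
}
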