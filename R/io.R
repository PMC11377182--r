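# Delimited-text serialization for the package's data objects. Everything is
# plain TSV so results travel between runs and tools without binary formats.

#' Read and write community vectors and trait matrices
#'
#' Communities are stored as two-column TSV (tip label, 0/1); trait matrices
#' as TSV with tip labels in the first column. Batch community matrices
#' (simulations x tips) are stored as TSV with tips as column headers.
#'
#' @param community Named 0/1 vector in tip order.
#' @param traits Numeric matrix with tip-label row names.
#' @param communities Simulations x tips 0/1 matrix with tip-label columns.
#' @param file Path to read or write.
#' @return The read functions return the corresponding object; write
#'   functions return the path invisibly.
#' @name text_io
NULL

#' @rdname text_io
#' @export
write_community <- function(community, file) {
  stopifnot(!is.null(names(community)))
  utils::write.table(
    data.frame(tip = names(community), present = as.integer(community)),
    file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname text_io
#' @export
read_community <- function(file) {
  d <- utils::read.table(file, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  stats::setNames(as.integer(d[[2]]), d[[1]])
}

#' @rdname text_io
#' @export
write_traits <- function(traits, file) {
  stopifnot(!is.null(rownames(traits)))
  utils::write.table(data.frame(tip = rownames(traits), traits),
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname text_io
#' @export
read_traits <- function(file) {
  d <- utils::read.table(file, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  colnames(m) <- NULL
  m
}

#' @rdname text_io
#' @export
write_communities <- function(communities, file) {
  stopifnot(!is.null(colnames(communities)))
  utils::write.table(communities, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname text_io
#' @export
read_communities <- function(file) {
  as.matrix(utils::read.table(file, header = TRUE, sep = "\t",
                              check.names = FALSE))
}

#' Read and write MPD curves and models as delimited text
#'
#' Curves are two-column TSV (grid value, SES-MPD) with the transformation
#' model recorded in a comment header; MPD models are coefficient tables.
#'
#' @param curve An `mpd_curve`.
#' @param model An `mpd_model`.
#' @param file Path to read or write.
#' @name curve_io
NULL

#' @rdname curve_io
#' @export
write_mpd_curve <- function(curve, file) {
  stopifnot(inherits(curve, "mpd_curve"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("# model\t", curve$grid$model), con)
  utils::write.table(data.frame(value = curve$grid$values,
                                ses_mpd = curve$values),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname curve_io
#' @export
read_mpd_curve <- function(file) {
  first <- readLines(file, n = 1)
  model <- sub("^# model\t", "", first)
  d <- utils::read.table(file, header = TRUE, sep = "\t", comment.char = "#")
  structure(list(grid = transform_grid(model, d$value),
                 values = d$ses_mpd),
            class = "mpd_curve")
}

#' @rdname curve_io
#' @export
write_mpd_model <- function(model, file) {
  stopifnot(inherits(model, "mpd_model"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("# model\t", model$grid$model), con)
  writeLines(paste0("# intercept\t", format(model$intercept, digits = 17)), con)
  utils::write.table(data.frame(value = model$grid$values,
                                coefficient = model$coefficients),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname curve_io
#' @export
read_mpd_model <- function(file) {
  hdr <- readLines(file, n = 2)
  model <- sub("^# model\t", "", hdr[1])
  intercept <- as.numeric(sub("^# intercept\t", "", hdr[2]))
  d <- utils::read.table(file, header = TRUE, sep = "\t", comment.char = "#")
  structure(list(intercept = intercept,
                 coefficients = d$coefficient,
                 grid = transform_grid(model, d$value)),
            class = "mpd_model")
}

#' Serialize a Convolutional Kitchen Sink model as delimited text
#'
#' The normal matrix is not stored: its seed and dimensions are, and
#' [make_norms()] regenerates it exactly, so predictions from a re-read model
#' are reproducible. Only models whose projection came from [make_norms()]
#' (i.e. carry a seed) can be serialized.
#'
#' @param model A `cks_model`.
#' @param file Path to read or write.
#' @export
write_cks_model <- function(model, file) {
  stopifnot(inherits(model, "cks_model"))
  seed <- attr(model$norms, "seed")
  if (is.null(seed)) {
    stop("only models built from a seeded make_norms() matrix can be serialized")
  }
  hdr <- c(w = attr(model$norms, "w"), f = attr(model$norms, "f"),
           seed = seed, penalty = model$penalty,
           intercept = model$intercept,
           y_min = model$y_range[1], y_max = model$y_range[2],
           input_length = model$input_length)
  con <- file(file, "w")
  on.exit(close(con))
  for (nm in names(hdr)) {
    writeLines(paste0("# ", nm, "\t", format(hdr[[nm]], digits = 17)), con)
  }
  utils::write.table(data.frame(beta = model$beta,
                                center = model$centers,
                                scale = model$scales),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_cks_model
#' @export
read_cks_model <- function(file) {
  lines <- readLines(file)
  hdr_lines <- grep("^# ", lines, value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^# ", "", hdr_lines), "\t"))
  hdr <- stats::setNames(as.numeric(kv[, 2]), kv[, 1])
  d <- utils::read.table(file, header = TRUE, sep = "\t", comment.char = "#")
  structure(list(norms = make_norms(hdr[["w"]], hdr[["f"]], hdr[["seed"]]),
                 beta = d$beta,
                 intercept = hdr[["intercept"]],
                 penalty = hdr[["penalty"]],
                 centers = d$center,
                 scales = d$scale,
                 y_range = c(hdr[["y_min"]], hdr[["y_max"]]),
                 input_length = as.integer(hdr[["input_length"]])),
            class = "cks_model")
}
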