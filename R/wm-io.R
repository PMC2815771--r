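#' Read and write weight matrices
#'
#' The on-disk format is a plain-text, tab-delimited 4 x W matrix: a `>name`
#' header line followed by four rows labelled `A`, `C`, `G`, `T`, one column
#' per motif position. `read_wm()` also accepts the transposed W x 4 layout
#' with a `#pos A C G T` header and one row per position.
#'
#' @param wm A [weight_matrix()].
#' @param path File path.
#' @return `read_wm()` returns a [weight_matrix()] (labelled from the header);
#'   `write_wm()` returns `path` invisibly.
#' @export
write_wm <- function(wm, path) {
  lines <- c(paste0(">", attr(wm, "label")),
             vapply(seq_len(4L), function(i)
               paste(c(DNA_BASES[i], format(unclass(wm)[i, ], digits = 17)),
                     collapse = "\t"),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_wm
#' @export
read_wm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("not a weight matrix file: ", path)
  header <- lines[[1L]]
  body <- lapply(strsplit(lines[-1L], "\t", fixed = TRUE), trimws)
  if (startsWith(header, ">")) {
    label <- sub("^>\\s*", "", header)
    if (length(body) != 4L) stop("expected 4 base rows in ", path)
    keys <- toupper(vapply(body, `[[`, character(1), 1L))
    if (!setequal(keys, DNA_BASES)) stop("base row labels must be A, C, G, T")
    vals <- lapply(body, function(x) as.numeric(x[-1L]))
    m <- do.call(rbind, vals)[match(DNA_BASES, keys), , drop = FALSE]
  } else if (startsWith(header, "#")) {
    cols <- strsplit(sub("^#\\s*", "", header), "\\s+")[[1L]]
    if (!identical(toupper(cols), c("POS", DNA_BASES)))
      stop("transposed weight matrix header must be '#pos A C G T'")
    label <- tools::file_path_sans_ext(basename(path))
    m <- vapply(body, function(x) as.numeric(x[2:5]), numeric(4))
    m <- m[, order(as.integer(vapply(body, `[[`, character(1), 1L))),
           drop = FALSE]
  } else {
    stop("weight matrix file must start with '>name' or '#pos A C G T'")
  }
  if (anyNA(m)) stop("malformed numeric entries in ", path)
  weight_matrix(m, label = label)
}
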