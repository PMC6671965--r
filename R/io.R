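#' Valued sociometric matrix
#'
#' A square non-negative valued matrix of directed nominations (e.g.
#' ranked "liking" choices), with optional actor labels.  The diagonal is
#' ignored.  Actor indices are 1-based and reported in the original file
#' order throughout, also after actors are dropped.
#'
#' @param v a square numeric matrix.
#' @param labels optional character vector of actor names.
#' @return a `valued_matrix`.
#' @export
valued_matrix <- function(v, labels = NULL) {
  v <- as.matrix(v)
  if (nrow(v) != ncol(v)) stop("matrix must be square", call. = FALSE)
  if (anyNA(v)) stop("values must not be NA", call. = FALSE)
  n <- nrow(v)
  if (!is.null(labels) && length(labels) != n) {
    stop("labels length must match the matrix size", call. = FALSE)
  }
  structure(v, labels = labels, orig_index = seq_len(n),
            class = c("valued_matrix", "matrix", "array"))
}

#' @export
print.valued_matrix <- function(x, ...) {
  cat(sprintf("<valued_matrix> %d actors\n", nrow(x)))
  m <- unclass(x)
  attr(m, "labels") <- NULL
  attr(m, "orig_index") <- NULL
  dimnames(m) <- list(attr(x, "orig_index"), attr(x, "orig_index"))
  print(m, ...)
  invisible(x)
}

#' Read a sociometric matrix
#'
#' Supported formats: UCINET DL in its full-matrix dialect (an `dl n=..`
#' header, optional `format = fullmatrix`, optional `labels:` block,
#' `data:` followed by the row-major matrix), and headerless numeric CSV.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"dl"` or `"csv"`.
#' @return a [valued_matrix()].
#' @export
read_sociomatrix <- function(path, format = c("auto", "dl", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.dl$", path, ignore.case = TRUE)) "dl" else "csv"
  }
  if (format == "csv") {
    m <- suppressMessages(readr::read_csv(path, col_names = FALSE,
                                          show_col_types = FALSE))
    m <- as.matrix(m)
    if (!is.numeric(m)) stop("CSV must be all numeric", call. = FALSE)
    dimnames(m) <- NULL
    return(valued_matrix(m))
  }
  read_dl(path)
}

read_dl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  perr <- function(lineno, msg) {
    stop(sprintf("%s:%d: %s", path, lineno, msg), call. = FALSE)
  }
  low <- tolower(trimws(lines))
  if (length(lines) == 0L || !grepl("^dl\\b", low[1])) {
    perr(1, "not a DL file (header must start with 'dl')")
  }
  header <- low[1]
  nm <- regmatches(header, regexpr("n\\s*=\\s*[0-9]+", header))
  if (length(nm) == 0L) perr(1, "missing n=<count> declaration")
  n <- as.integer(sub("n\\s*=\\s*", "", nm))

  fmt_line <- grep("^format", low)
  if (length(fmt_line) > 0L &&
      !grepl("fullmatrix", low[fmt_line[1]])) {
    perr(fmt_line[1],
         "only the full-matrix DL dialect is supported")
  }

  labels <- NULL
  lab_start <- grep("^(row |col |column )?labels\\s*:", low)
  data_start <- grep("^data\\s*:", low)
  if (length(data_start) == 0L) perr(length(lines), "missing 'data:' section")
  data_start <- data_start[1]
  if (length(lab_start) > 0L) {
    l0 <- lab_start[1]
    stop_at <- min(c(lab_start[-1], data_start)) - 1L
    lab_text <- paste(lines[(l0 + 1):stop_at], collapse = " ")
    labels <- strsplit(trimws(lab_text), "[,[:space:]]+")[[1]]
    labels <- labels[nzchar(labels)]
    labels <- gsub('^"|"$', "", labels)
    if (length(labels) != n) {
      perr(l0, sprintf("expected %d labels, found %d", n, length(labels)))
    }
  }

  data_text <- paste(lines[(data_start + 1):length(lines)], collapse = " ")
  vals <- suppressWarnings(
    as.numeric(strsplit(trimws(data_text), "[,[:space:]]+")[[1]]))
  if (anyNA(vals)) perr(data_start + 1, "non-numeric value in data section")
  if (length(vals) != n * n) {
    perr(data_start + 1,
         sprintf("expected %d values (%d x %d), found %d",
                 n * n, n, n, length(vals)))
  }
  valued_matrix(matrix(vals, n, n, byrow = TRUE), labels = labels)
}

#' Write a valued matrix in DL full-matrix format
#'
#' @param m a [valued_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dl <- function(m, path) {
  n <- nrow(m)
  lines <- c(sprintf("dl n=%d", n), "format = fullmatrix")
  labels <- attr(m, "labels")
  if (!is.null(labels)) {
    lines <- c(lines, "labels:", paste(labels, collapse = ","))
  }
  lines <- c(lines, "data:",
             apply(unclass(m), 1, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Combine positive and negative nomination matrices
#'
#' Builds the signed continuous relation matrix `(x - y) / scale`, the
#' positive-minus-negative nominations scaled into `(-1, 1)`.
#'
#' @param x,y [valued_matrix()] objects of the same size (positive and
#'   negative nominations).
#' @param scale divisor keeping the result in `[-1, 1]`.
#' @return a [relation_matrix()]; labels and original indices of `x` are
#'   carried along as attributes.
#' @export
combine_signed <- function(x, y, scale = 5) {
  if (!all(dim(x) == dim(y))) {
    stop("matrices must have the same shape", call. = FALSE)
  }
  d <- (unclass(x) - unclass(y)) / scale
  diag(d) <- 0
  if (max(abs(d)) > 1) {
    stop(sprintf(
      "|x - y| exceeds scale = %g somewhere; result would leave [-1, 1]",
      scale), call. = FALSE)
  }
  out <- relation_matrix(d)
  attr(out, "labels") <- attr(x, "labels")
  attr(out, "orig_index") <- attr(x, "orig_index") %||% seq_len(nrow(x))
  out
}

#' Drop actors from a matrix
#'
#' Removes the given rows/columns (indices refer to the ORIGINAL file
#' ordering).  Labels and the original-index bookkeeping are updated so
#' later reports still name actors by their original position.
#'
#' @param m a [valued_matrix()] or [relation_matrix()].
#' @param indices original 1-based actor indices to remove.
#' @return the reduced matrix of the same class.
#' @export
drop_actors <- function(m, indices) {
  if (length(indices) == 0L) return(m)
  orig <- attr(m, "orig_index") %||% seq_len(nrow(m))
  keep <- which(!(orig %in% indices))
  if (length(keep) == length(orig)) return(m)
  if (length(keep) < 3L) {
    stop("fewer than 3 actors would remain", call. = FALSE)
  }
  v <- unclass(m)[keep, keep, drop = FALSE]
  labels <- attr(m, "labels")
  if (inherits(m, "valued_matrix")) {
    out <- valued_matrix(v, labels = labels[keep])
  } else {
    out <- relation_matrix(v)
    attr(out, "labels") <- labels[keep]
  }
  attr(out, "orig_index") <- orig[keep]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full analysis of a sociometric relation matrix
#'
#' Evolves the given continuous relations to a corner, classifies the
#' terminal state, identifies the archetype and computes each actor's
#' self-evaluation index.  Non-convergence (the data not dense enough to
#' freeze into a fully connected +/-1 state) is reported, not raised.
#'
#' @param r a [relation_matrix()], e.g. from [combine_signed()].
#' @param tol,t_max passed to [evolve()].
#' @return a `sociomatrix_report`: list with `converged`, `evolution`,
#'   and, when converged, `graph` (the `class_graph`), `template`
#'   ([template_spec()] or `NULL`), and `actors` (tibble: `actor` =
#'   original index, `label`, `class`, `f`, `low_self_evaluation`).
#' @export
analyze_sociomatrix <- function(r, tol = 1e-8, t_max = 1000) {
  if (!inherits(r, "relation_matrix")) r <- relation_matrix(r)
  orig <- attr(r, "orig_index") %||% seq_len(nrow(r))
  labels <- attr(r, "labels")
  ev <- evolve(r, tol = tol, t_max = t_max)
  out <- list(converged = ev$converged, evolution = ev, graph = NULL,
              template = NULL, actors = NULL)
  class(out) <- "sociomatrix_report"
  if (!ev$converged) return(out)
  s <- ev$sign
  p <- refine_classes(s)
  g <- class_graph(s, p)
  out$graph <- g
  out$template <- identify_template(g)
  fe <- self_evaluation(s)
  out$actors <- tibble::tibble(
    actor = orig,
    label = if (is.null(labels)) NA_character_ else labels,
    class = p$membership,
    f = fe$f,
    low_self_evaluation = fe$f < 0)
  out
}

#' @export
print.sociomatrix_report <- function(x, ...) {
  if (!x$converged) {
    cat("<sociomatrix_report> did not converge ",
        "(matrix not dense enough to freeze)\n", sep = "")
    return(invisible(x))
  }
  kind <- if (is.null(x$template)) "other" else x$template$kind
  cat(sprintf("<sociomatrix_report> converged; archetype %s, sizes (%s)\n",
              kind, paste(x$graph$sizes, collapse = ", ")))
  low <- x$actors[x$actors$low_self_evaluation, ]
  if (nrow(low) > 0L) {
    cat("actors with negative self-evaluation:",
        paste(low$actor, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Per-actor table of a sociomatrix report
#' @param x a `sociomatrix_report`.
#' @param ... unused.
#' @export
tidy.sociomatrix_report <- function(x, ...) {
  if (is.null(x$actors)) {
    stop("the evolution did not converge; no per-actor table",
         call. = FALSE)
  }
  x$actors
}
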