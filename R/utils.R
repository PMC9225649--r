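`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resolve a dotted parameter path inside a model configuration
#'
#' Paths mirror the configuration layout, e.g. `"markov_utilities.u_controlled"`
#' or, for adverse-event rows, `"adverse_events.<item>.<column>"` where
#' `<item>` is the snake_case event name.
#'
#' @param cfg a `cua_config` object (or any nested list)
#' @param path character scalar, components separated by `.`
#' @return the value stored at `path`
#' @keywords internal
cfg_get <- function(cfg, path) {
  toks <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- cfg
  i <- 1L
  while (i <= length(toks)) {
    if (is.data.frame(node)) {
      key <- snake_case(node$name)
      row <- match(toks[i], key)
      if (is.na(row)) stop("parameter path not found: ", path, call. = FALSE)
      col <- toks[i + 1L]
      if (is.na(col) || !col %in% names(node))
        stop("parameter path not found: ", path, call. = FALSE)
      return(node[[col]][row])
    }
    if (!is.list(node) || is.null(node[[toks[i]]]))
      stop("parameter path not found: ", path, call. = FALSE)
    node <- node[[toks[i]]]
    i <- i + 1L
  }
  node
}

#' @rdname cfg_get
#' @param value replacement value
#' @keywords internal
cfg_set <- function(cfg, path, value) {
  toks <- strsplit(path, ".", fixed = TRUE)[[1]]
  set_rec <- function(node, toks) {
    if (is.data.frame(node)) {
      key <- snake_case(node$name)
      row <- match(toks[1L], key)
      if (is.na(row) || length(toks) != 2L || !toks[2L] %in% names(node))
        stop("parameter path not found: ", path, call. = FALSE)
      node[[toks[2L]]][row] <- value
      return(node)
    }
    if (!is.list(node) || !toks[1L] %in% names(node))
      stop("parameter path not found: ", path, call. = FALSE)
    if (length(toks) == 1L) {
      node[[toks[1L]]] <- value
    } else {
      node[[toks[1L]]] <- set_rec(node[[toks[1L]]], toks[-1L])
    }
    node
  }
  out <- set_rec(unclass(cfg), toks)
  class(out) <- class(cfg)
  out
}

snake_case <- function(x) {
  x <- tolower(gsub("[^A-Za-z0-9]+", "_", x))
  gsub("^_|_$", "", x)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
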