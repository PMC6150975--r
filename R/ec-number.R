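#' Enzyme Commission number algebra
#'
#' An EC number is a four-component hierarchical identifier
#' (main class . subclass . sub-subclass . substrate); trailing components
#' may be the wildcard `-`, so `1.1.-.-` denotes the whole subclass 1.1.
#' The *level* of an EC number is the count of leading numeric components
#' (0 for the virtual root `-.-.-.-`, 4 for a fully specified number).
#' Wildcards are suffix-only: a numeric component may never follow a
#' wildcard.
#'
#' @param text an EC string such as `"1.1.2.4"` or `"2.-.-.-"`.
#' @return `ec_parse()` returns an object of class `ec_number`, a list
#'   with integer `components` (NA marks a wildcard) and `level`.
#' @examples
#' ec <- ec_parse("1.1.2.4")
#' ec_level(ec)            # 4
#' ec_format(ec_parent(ec))  # "1.1.2.-"
#' ec_relation("1.1.-.-", "1.2.-.-")  # "sibling"
#' @export
ec_parse <- function(text) {
  if (inherits(text, "ec_number")) return(text)
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("EC number must be a single string")
  }
  tokens <- strsplit(text, ".", fixed = TRUE)[[1]]
  if (length(tokens) != 4L) {
    stop("invalid EC number '", text, "': expected 4 dot-separated components")
  }
  comp <- rep(NA_integer_, 4L)
  for (i in seq_len(4L)) {
    tok <- tokens[i]
    if (tok == "-") next
    if (!grepl("^[0-9]+$", tok) || as.integer(tok) < 1L) {
      stop("invalid EC number '", text, "': component '", tok,
           "' is neither a positive integer nor '-'")
    }
    comp[i] <- as.integer(tok)
  }
  lev <- ec_level_from_components(comp, text)
  structure(list(components = comp, level = lev), class = "ec_number")
}

ec_level_from_components <- function(comp, text = NULL) {
  wild <- is.na(comp)
  if (any(wild)) {
    first <- which(wild)[1]
    if (any(!wild[first:4L])) {
      stop("invalid EC number '",
           if (is.null(text)) paste(ifelse(wild, "-", comp), collapse = ".") else text,
           "': numeric component after a wildcard")
    }
    first - 1L
  } else 4L
}

#' @rdname ec_parse
#' @param ec an `ec_number` or EC string.
#' @export
ec_format <- function(ec) {
  ec <- ec_parse(ec)
  paste(ifelse(is.na(ec$components), "-", ec$components), collapse = ".")
}

#' @export
format.ec_number <- function(x, ...) ec_format(x)

#' @export
print.ec_number <- function(x, ...) {
  cat("<EC ", ec_format(x), "> level ", x$level, "\n", sep = "")
  invisible(x)
}

#' @rdname ec_parse
#' @export
ec_level <- function(ec) ec_parse(ec)$level

#' @rdname ec_parse
#' @details `ec_parent()` returns the EC number one level up
#'   (`NULL` for the level-0 root).
#' @export
ec_parent <- function(ec) {
  ec <- ec_parse(ec)
  if (ec$level == 0L) return(NULL)
  comp <- ec$components
  comp[ec$level] <- NA_integer_
  structure(list(components = comp, level = ec$level - 1L),
            class = "ec_number")
}

#' @rdname ec_parse
#' @param include_self include the number itself in the ancestor list.
#' @details `ec_ancestors()` lists the proper ancestors from the direct
#'   parent up to level 1 (the root is excluded).
#' @export
ec_ancestors <- function(ec, include_self = FALSE) {
  ec <- ec_parse(ec)
  out <- if (include_self && ec$level >= 1L) list(ec) else list()
  p <- ec_parent(ec)
  while (!is.null(p) && p$level >= 1L) {
    out <- c(out, list(p))
    p <- ec_parent(p)
  }
  out
}

#' @rdname ec_parse
#' @param level target level, at most the number's own level.
#' @details `ec_truncate()` cuts an EC number down to the given level.
#' @export
ec_truncate <- function(ec, level) {
  ec <- ec_parse(ec)
  stopifnot(level >= 0L, level <= 4L)
  if (level >= ec$level) return(ec)
  comp <- ec$components
  if (level < 4L) comp[(level + 1L):4L] <- NA_integer_
  structure(list(components = comp, level = as.integer(level)),
            class = "ec_number")
}

#' Relation between two EC numbers
#'
#' @param a,b EC numbers (objects or strings).
#' @return One of `"self"`, `"ancestor"` (a is a proper ancestor of b),
#'   `"descendant"`, `"sibling"` (same level, same parent, different last
#'   component), or `"unrelated"`.
#' @export
ec_relation <- function(a, b) {
  a <- ec_parse(a); b <- ec_parse(b)
  la <- a$level; lb <- b$level
  pref <- function(x, k) if (k == 0L) integer(0) else x$components[seq_len(k)]
  if (la == lb && identical(pref(a, la), pref(b, lb))) return("self")
  if (la < lb && identical(pref(a, la), pref(b, la))) return("ancestor")
  if (lb < la && identical(pref(b, lb), pref(a, lb))) return("descendant")
  if (la == lb && la >= 1L &&
      identical(pref(a, la - 1L), pref(b, lb - 1L))) return("sibling")
  "unrelated"
}

# Ordering key: level first, then components (wildcards last).
ec_sort_strings <- function(ecs) {
  parsed <- lapply(ecs, ec_parse)
  lev <- vapply(parsed, function(e) e$level, integer(1))
  comp <- t(vapply(parsed, function(e) {
    x <- e$components; x[is.na(x)] <- 0L; x
  }, integer(4)))
  ord <- order(lev, comp[, 1], comp[, 2], comp[, 3], comp[, 4])
  ecs[ord]
}

ec_main_class <- function(ec) ec_parse(ec)$components[1]
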