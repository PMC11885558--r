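# AAMI beat-class schemes and segment labelling.

# MIT-BIH annotation symbols that denote beats (everything else is a
# rhythm/quality/auxiliary mark and is dropped before labelling).
.BEAT_SYMBOLS <- c("N", "L", "R", "B", "A", "a", "J", "S", "V", "r",
                   "F", "e", "j", "n", "E", "/", "f", "Q", "?")

.AAMI_SYMBOL_MAP <- c(
  # normal / bundle-branch / escape
  "N" = "N", "L" = "N", "R" = "N", "e" = "N", "j" = "N", "B" = "N",
  # supraventricular ectopic
  "A" = "S", "a" = "S", "S" = "S", "J" = "S", "n" = "S",
  # ventricular ectopic
  "V" = "V", "E" = "V", "r" = "V",
  # fusion
  "F" = "F",
  # paced / fusion-of-paced / unclassified
  "/" = "Q", "f" = "Q", "Q" = "Q", "?" = "Q", "U" = "Q"
)

#' Beat-class schemes
#'
#' A class scheme names the active set of AAMI beat classes, the mapping
#' from single-character annotation symbols to those classes, and the
#' priority order used to break ties when a segment contains several
#' abnormal beat classes equally often.
#'
#' Two ready-made schemes are provided: `"mitbih"` (five classes
#' N, S, V, F, Q) and `"icentia"` (four classes N, S, V, Q; fusion beats
#' fold into V, matching the four-class labelling of long-term Holter
#' data).
#'
#' @param name `"mitbih"` or `"icentia"`.
#' @return An object of class `class_scheme`: a list with `labels`,
#'   `symbol_map` (named character vector), and `tie_priority`.
#' @examples
#' sch <- class_scheme("mitbih")
#' map_symbol("L", sch)   # left bundle branch block beat -> "N"
#' @export
class_scheme <- function(name = c("mitbih", "icentia")) {
  name <- match.arg(name)
  if (name == "mitbih") {
    labels <- c("N", "S", "V", "F", "Q")
    map <- .AAMI_SYMBOL_MAP
  } else {
    labels <- c("N", "S", "V", "Q")
    map <- .AAMI_SYMBOL_MAP
    map[map == "F"] <- "V"   # no fusion class: fold into ventricular
  }
  structure(
    list(name = name, labels = labels, symbol_map = map,
         tie_priority = intersect(c("V", "S", "F", "Q"), labels)),
    class = "class_scheme"
  )
}

#' @export
print.class_scheme <- function(x, ...) {
  cat("<class_scheme ", x$name, "> labels: ", paste(x$labels, collapse = ", "),
      "; tie priority: ", paste(x$tie_priority, collapse = " > "), "\n", sep = "")
  invisible(x)
}

#' Map an annotation symbol to its AAMI class
#'
#' Total function: known beat symbols map per the scheme, unknown beat
#' codes fall back to `"Q"`, and non-beat annotation symbols (rhythm
#' changes, signal-quality marks, auxiliary notes) return `NA_character_`
#' so callers can drop them before labelling.
#'
#' @param symbol character vector of single-character annotation codes.
#' @param scheme a [class_scheme()].
#' @return Character vector of class labels, `NA` for non-beat symbols.
#' @export
map_symbol <- function(symbol, scheme = class_scheme("mitbih")) {
  stopifnot(inherits(scheme, "class_scheme"))
  out <- rep(NA_character_, length(symbol))
  is_beat <- symbol %in% .BEAT_SYMBOLS | symbol %in% names(scheme$symbol_map)
  mapped <- unname(scheme$symbol_map[symbol[is_beat]])
  mapped[is.na(mapped)] <- "Q"   # beat-like but unmapped -> unclassified
  out[is_beat] <- mapped
  out
}

#' Label a segment from the beat classes it contains
#'
#' Policy: an empty segment is excluded (`NA`); an all-normal segment is
#' `"N"`; otherwise the most frequent abnormal (non-N) class wins, with
#' ties broken by `scheme$tie_priority` (default V > S > F > Q).
#' The result is invariant to the order of `classes`.
#'
#' @param classes character vector of per-beat AAMI classes inside the
#'   segment's half-open sample interval (non-beat `NA`s are ignored).
#' @param scheme a [class_scheme()].
#' @param policy `"majority"` (default), `"any_abnormal"` (first
#'   abnormal class by tie priority regardless of count), or
#'   `"strict_uniform"` (label only if all beats agree, else exclude).
#' @return A single class label, or `NA_character_` for "exclude".
#' @export
label_segment <- function(classes, scheme = class_scheme("mitbih"),
                          policy = c("majority", "any_abnormal", "strict_uniform")) {
  policy <- match.arg(policy)
  classes <- classes[!is.na(classes)]
  if (length(classes) == 0L) return(NA_character_)
  if (policy == "strict_uniform") {
    u <- unique(classes)
    return(if (length(u) == 1L) u else NA_character_)
  }
  abn <- classes[classes != "N"]
  if (length(abn) == 0L) return("N")
  if (policy == "any_abnormal") {
    for (cl in scheme$tie_priority) if (cl %in% abn) return(cl)
    return(abn[[1L]])
  }
  counts <- table(abn)
  top <- names(counts)[counts == max(counts)]
  if (length(top) == 1L) return(top)
  for (cl in scheme$tie_priority) if (cl %in% top) return(cl)
  top[[1L]]
}
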