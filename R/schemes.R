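#' Sleep stage schemes
#'
#' A stage scheme declares the label set used for staging. Five-class is the
#' AASM scoring vocabulary (W, N1, N2, N3, REM); four-class merges N1 and N2
#' into Light and renames N3 to Deep; three-class merges all NREM stages;
#' two-class is sleep/wake.
#'
#' @param name One of `"two"`, `"three"`, `"four"`, `"five"`.
#' @return A `stage_scheme` object with elements `name`, `labels` (ordered
#'   character vector) and `K` (number of classes).
#' @examples
#' stage_scheme("four")$labels  # "W" "Light" "Deep" "REM"
#' @export
stage_scheme <- function(name = c("four", "three", "five", "two")) {
  name <- match.arg(name)
  labels <- switch(name,
    five  = c("W", "N1", "N2", "N3", "REM"),
    four  = c("W", "Light", "Deep", "REM"),
    three = c("W", "NREM", "REM"),
    two   = c("W", "Sleep"))
  structure(list(name = name, labels = labels, K = length(labels)),
            class = "stage_scheme")
}

#' @export
print.stage_scheme <- function(x, ...) {
  cat(sprintf("<stage_scheme '%s'> K=%d: %s\n",
              x$name, x$K, paste(x$labels, collapse = ", ")))
  invisible(x)
}

#' Collapse stage labels from one scheme onto a coarser one
#'
#' Collapsing maps are surjective and order-consistent: N1+N2 -> Light,
#' N3 -> Deep, N1+N2+N3 -> NREM, all non-wake -> Sleep.
#'
#' @param labels Character vector of stage labels valid under `from`.
#' @param from,to `stage_scheme` objects; `to` must be coarser than `from`.
#' @return Character vector of labels under `to`.
#' @export
collapse_stages <- function(labels, from, to) {
  stopifnot(inherits(from, "stage_scheme"), inherits(to, "stage_scheme"))
  rank <- c(two = 2, three = 3, four = 4, five = 5)
  if (rank[[to$name]] > rank[[from$name]])
    stop("'to' scheme must be coarser than or equal to 'from'")
  bad <- setdiff(unique(labels), from$labels)
  if (length(bad))
    stop("labels not in scheme '", from$name, "': ", paste(bad, collapse = ", "))
  map <- stage_collapse_map(from, to)
  unname(map[labels])
}

stage_collapse_map <- function(from, to) {
  # route every label through the five-class vocabulary
  to_five <- c(W = "W", N1 = "N1", N2 = "N2", N3 = "N3", REM = "REM",
               Light = "N1", Deep = "N3", NREM = "N2", Sleep = "N2")
  five_to <- switch(to$name,
    five  = c(W = "W", N1 = "N1", N2 = "N2", N3 = "N3", REM = "REM"),
    four  = c(W = "W", N1 = "Light", N2 = "Light", N3 = "Deep", REM = "REM"),
    three = c(W = "W", N1 = "NREM", N2 = "NREM", N3 = "NREM", REM = "REM"),
    two   = c(W = "W", N1 = "Sleep", N2 = "Sleep", N3 = "Sleep", REM = "Sleep"))
  out <- five_to[to_five[from$labels]]
  names(out) <- from$labels
  out
}

#' Test whether a label denotes sleep (anything but wake)
#' @param labels Character vector of stage labels.
#' @return Logical vector.
#' @export
is_sleep_stage <- function(labels) labels != "W"

#' Construct a hypnogram
#'
#' A hypnogram is the per-epoch sequence of stage labels over one night,
#' tagged with its stage scheme and epoch duration.
#'
#' @param labels Character vector of stage labels.
#' @param scheme A `stage_scheme`.
#' @param epoch_s Epoch duration in seconds (default 30).
#' @return A `hypnogram` object (character vector with attributes).
#' @export
hypnogram <- function(labels, scheme, epoch_s = 30) {
  stopifnot(inherits(scheme, "stage_scheme"))
  bad <- setdiff(unique(labels), scheme$labels)
  if (length(bad))
    stop("labels not in scheme '", scheme$name, "': ", paste(bad, collapse = ", "))
  structure(as.character(labels), scheme = scheme, epoch_s = epoch_s,
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  sch <- attr(x, "scheme")
  tab <- table(factor(unclass(x), levels = sch$labels))
  cat(sprintf("<hypnogram> %d epochs of %gs, scheme '%s'\n",
              length(x), attr(x, "epoch_s"), sch$name))
  print(round(100 * tab / length(x), 1))
  invisible(x)
}

hyp_scheme <- function(hyp) attr(hyp, "scheme")
hyp_epoch_s <- function(hyp) attr(hyp, "epoch_s") %||% 30

`%||%` <- function(a, b) if (is.null(a)) b else a
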