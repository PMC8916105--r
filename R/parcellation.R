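#' Cortical parcellation with lobe grouping and eloquent labels
#'
#' A Desikan-Killiany-style labelling of the template vertices. Every vertex
#' carries exactly one label; every label belongs to one of six lobes
#' (frontal, temporal, parietal, occipital, cingulate, insula). A subset of
#' labels is designated eloquent cortex: motor and visual labels apply to
#' both hemispheres, language labels to the left hemisphere only.
#'
#' @param label_per_vertex integer vector, one label id per vertex (ids index
#'   into `label_names`).
#' @param label_names character vector of label names, position = label id.
#' @param lobe_of_label named character vector mapping label name to lobe.
#' @param eloquent_bilateral,eloquent_left_only character vectors of label
#'   names forming the eloquent-cortex mask; defaults are the standard
#'   motor/visual and left-lateralised language labels.
#'
#' @return an object of class `parcellation`.
#' @export
parcellation <- function(label_per_vertex, label_names, lobe_of_label,
                         eloquent_bilateral = ELOQUENT_BILATERAL,
                         eloquent_left_only = ELOQUENT_LEFT_ONLY) {
  label_per_vertex <- as.integer(label_per_vertex)
  if (anyNA(label_per_vertex) || any(label_per_vertex < 1L) ||
      any(label_per_vertex > length(label_names)))
    stop("every vertex must carry a valid label id")
  lobes <- c("frontal", "temporal", "parietal", "occipital",
             "cingulate", "insula")
  if (!all(label_names %in% names(lobe_of_label)))
    stop("every label must map to a lobe")
  if (!all(lobe_of_label %in% lobes))
    stop("lobes must be one of: ", paste(lobes, collapse = ", "))
  structure(
    list(label_per_vertex = label_per_vertex,
         label_names = label_names,
         lobe_of_label = lobe_of_label[label_names],
         eloquent_bilateral = eloquent_bilateral,
         eloquent_left_only = eloquent_left_only),
    class = "parcellation")
}

#' Standard eloquent-cortex label names
#'
#' Motor (precentral) and visual (pericalcarine, lateraloccipital, cuneus,
#' lingual) labels count as eloquent in both hemispheres; the language labels
#' (parsopercularis, parstriangularis, transversetemporal) only on the left.
#'
#' @format character vectors of Desikan-Killiany label names.
#' @export
ELOQUENT_BILATERAL <- c("precentral", "pericalcarine", "lateraloccipital",
                        "cuneus", "lingual")

#' @rdname ELOQUENT_BILATERAL
#' @export
ELOQUENT_LEFT_ONLY <- c("parsopercularis", "parstriangularis",
                        "transversetemporal")

#' @export
print.parcellation <- function(x, ...) {
  cat("parcellation:", length(x$label_per_vertex), "vertices,",
      length(x$label_names), "labels,",
      length(unique(x$lobe_of_label)), "lobes\n")
  invisible(x)
}

#' Per-vertex lobe assignment
#' @param parc a [parcellation()].
#' @return character vector, lobe name per vertex.
#' @export
lobe_per_vertex <- function(parc) {
  unname(parc$lobe_of_label[parc$label_per_vertex])
}

#' Binary eloquent-cortex mask
#'
#' Union of the eloquent labels for the requested hemisphere: the bilateral
#' motor/visual labels always, plus the language labels when
#' `hemisphere == "left"`.
#'
#' @param parc a [parcellation()].
#' @param hemisphere `"left"` or `"right"`.
#' @return integer 0/1 vector over vertices.
#' @export
eloquent_mask <- function(parc, hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  wanted <- parc$eloquent_bilateral
  if (hemisphere == "left") wanted <- c(wanted, parc$eloquent_left_only)
  absent <- setdiff(wanted, parc$label_names)
  if (length(absent))
    stop("parcellation lacks eloquent label(s): ",
         paste(absent, collapse = ", "))
  ids <- match(wanted, parc$label_names)
  as.integer(parc$label_per_vertex %in% ids)
}
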