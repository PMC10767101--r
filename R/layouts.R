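#' Tooth classes and landmark layouts
#'
#' A tooth class is the combination of arcade (maxillary/mandibular) and
#' position along the row (I1, I2, C, P3, P4, M1, M2, M3). The class fixes the
#' landmarking layout: postcanine teeth carry fixed dentine-horn landmarks and
#' an EDJ marginal-ridge ring split into sections between consecutive horns,
#' while anterior teeth (incisors, canines) carry the cervical (CEJ) ring only.
#'
#' @param position_label One of `"I1"`, `"I2"`, `"C"`, `"P3"`, `"P4"`, `"M1"`,
#'   `"M2"`, `"M3"`.
#' @param arcade `"maxillary"` or `"mandibular"`.
#' @return An object of class `tooth_class` with fields `arcade`, `family`
#'   (incisor/canine/premolar/molar) and `position_label`.
#' @examples
#' tooth_class("P3", "mandibular")
#' @export
tooth_class <- function(position_label, arcade = c("mandibular", "maxillary")) {
  arcade <- match.arg(arcade)
  positions <- c("I1", "I2", "C", "P3", "P4", "M1", "M2", "M3")
  if (!position_label %in% positions) {
    stop("unknown tooth position label: ", position_label)
  }
  family <- switch(substr(position_label, 1, 1),
    I = "incisor", C = "canine", P = "premolar", M = "molar")
  structure(
    list(arcade = arcade, family = family, position_label = position_label),
    class = "tooth_class"
  )
}

#' @export
print.tooth_class <- function(x, ...) {
  cat(sprintf("<tooth_class> %s %s (%s)\n", x$arcade, x$position_label, x$family))
  invisible(x)
}

is_postcanine <- function(tooth) tooth$family %in% c("premolar", "molar")

#' Fixed-cusp (dentine horn) names for a tooth class
#'
#' Cusp order follows the conventional digitising order: premolars carry two
#' horns, molars four; anterior teeth carry none.
#'
#' @param tooth A [tooth_class()].
#' @return Character vector of cusp names (possibly empty).
#' @export
cusp_names <- function(tooth) {
  if (!is_postcanine(tooth)) return(character(0))
  if (tooth$family == "premolar") {
    if (tooth$arcade == "mandibular") c("protoconid", "metaconid")
    else c("protocone", "metacone")
  } else {
    if (tooth$arcade == "mandibular") c("protoconid", "metaconid", "entoconid", "hypoconid")
    else c("protocone", "paracone", "metacone", "hypocone")
  }
}

#' Landmark layout of a tooth class
#'
#' Encodes the fixed landmark counts used throughout: premolars have 2 fixed
#' cusp landmarks and two EDJ ridge sections of 20 and 25 semilandmarks; molars
#' have 4 fixed cusp landmarks and four ridge sections of 20; every class has a
#' 40-landmark CEJ ring; anterior teeth have no fixed or ridge landmarks.
#' Total landmark counts are therefore 87 (premolar), 124 (molar), 40
#' (anterior).
#'
#' @param tooth A [tooth_class()].
#' @return An object of class `landmark_layout` with fields `n_fixed`,
#'   `ridge_section_counts`, `n_cej`, `fixed_names`, `n_total`.
#' @examples
#' landmark_layout(tooth_class("M1", "mandibular"))$n_total  # 124
#' @export
landmark_layout <- function(tooth) {
  stopifnot(inherits(tooth, "tooth_class"))
  fixed_names <- cusp_names(tooth)
  ridge <- switch(tooth$family,
    premolar = c(20L, 25L),
    molar = rep(20L, 4L),
    integer(0)
  )
  n_fixed <- length(fixed_names)
  layout <- structure(
    list(
      tooth = tooth,
      n_fixed = n_fixed,
      ridge_section_counts = ridge,
      n_cej = 40L,
      fixed_names = fixed_names,
      n_total = n_fixed + sum(ridge) + 40L
    ),
    class = "landmark_layout"
  )
  layout
}

#' @export
print.landmark_layout <- function(x, ...) {
  cat(sprintf(
    "<landmark_layout> %s %s: %d fixed + ridge [%s] + %d CEJ = %d landmarks\n",
    x$tooth$arcade, x$tooth$position_label, x$n_fixed,
    paste(x$ridge_section_counts, collapse = ","), x$n_cej, x$n_total
  ))
  invisible(x)
}

#' Index map for a homologous configuration
#'
#' Named, disjoint index slices covering `1:n_total` in storage order: fixed
#' cusp landmarks first, then each ridge section in cusp order, then the CEJ
#' ring.
#'
#' @param layout A [landmark_layout()].
#' @return Named list of integer vectors (`fixed`, `ridge1`..., `cej`).
#' @export
layout_index_map <- function(layout) {
  stopifnot(inherits(layout, "landmark_layout"))
  idx <- list()
  at <- 0L
  idx$fixed <- if (layout$n_fixed > 0) seq_len(layout$n_fixed) else integer(0)
  at <- layout$n_fixed
  for (j in seq_along(layout$ridge_section_counts)) {
    n <- layout$ridge_section_counts[j]
    idx[[paste0("ridge", j)]] <- at + seq_len(n)
    at <- at + n
  }
  idx$cej <- at + seq_len(layout$n_cej)
  idx
}

# ring orderings used for sliding tangents: list of integer vectors, each a
# closed ring in traversal order. For postcanines the EDJ ring interleaves
# fixed cusps with their sections; the CEJ ring is its own closed ring.
layout_rings <- function(layout) {
  im <- layout_index_map(layout)
  rings <- list()
  if (layout$n_fixed > 0) {
    ridge_ring <- integer(0)
    for (j in seq_along(layout$ridge_section_counts)) {
      ridge_ring <- c(ridge_ring, im$fixed[j], im[[paste0("ridge", j)]])
    }
    rings$ridge <- ridge_ring
  }
  rings$cej <- im$cej
  rings
}
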