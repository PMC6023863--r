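#' The four diastereomeric states
#'
#' The photoswitch studied by this package has a central C=C double bond
#' (Z or E) and an adjacent stable chiral axis, giving four thermally stable
#' diastereomers labelled `A`, `B`, `C`, `D`. The fixed order `A < B < C < D`
#' defines the row/column order of every matrix in the package.
#'
#' @return Character vector `c("A", "B", "C", "D")`.
#' @export
#' @examples
#' isomer_levels()
isomer_levels <- function() c("A", "B", "C", "D")

.stereo_table <- tibble::tibble(
  label = c("A", "B", "C", "D"),
  double_bond = c("Z", "Z", "E", "E"),
  axis = c("ax1", "ax2", "ax1", "ax2")
)

check_isomer <- function(label, name = "label") {
  if (!is.character(label) || any(!label %in% isomer_levels())) {
    abort_validation(sprintf(
      "`%s` must be one of \"A\", \"B\", \"C\", \"D\".", name
    ))
  }
  invisible(label)
}

#' Stereodescriptors of an isomer label
#'
#' Maps each state label to its double-bond configuration (`Z`/`E`) and an
#' abstract axial-chirality label (`ax1`/`ax2`). `A` and `B` share the `Z`
#' double bond with opposite axial chirality; `C` and `D` are the
#' corresponding `E` atropisomer pair. Absolute R/S and P/M assignments play
#' no role in any computation and are deliberately not modelled.
#'
#' @param label Character vector of state labels in `A`-`D`.
#' @return A tibble with columns `label`, `double_bond`, `axis`.
#' @export
#' @examples
#' stereo_of(c("A", "C"))
stereo_of <- function(label) {
  check_isomer(label)
  dplyr::left_join(tibble::tibble(label = label), .stereo_table, by = "label")
}

#' Classify a state-to-state photoreaction by motion type
#'
#' A transition that changes only the axial chirality is a single-bond
#' rotation (`SBR`); changing only the Z/E configuration is a double-bond
#' isomerization (`DBI`); changing both is a hula twist (`HT`). The identity
#' transition is `NONE`. Classification is symmetric in its arguments. Under
#' the fixed stereo assignment the SBR pairs are \{A,B\} and \{C,D\}, the DBI
#' pairs \{A,C\} and \{B,D\}, and the HT pairs \{A,D\} and \{B,C\}.
#'
#' @param src,dst Character vectors of state labels (recycled to a common
#'   length).
#' @return Character vector with elements in `c("SBR", "DBI", "HT", "NONE")`.
#' @export
#' @examples
#' classify_motion("A", "B") # SBR
#' classify_motion("B", "C") # HT
classify_motion <- function(src, dst) {
  check_isomer(src, "src")
  check_isomer(dst, "dst")
  n <- max(length(src), length(dst))
  src <- rep_len(src, n)
  dst <- rep_len(dst, n)
  s <- .stereo_table[match(src, .stereo_table$label), ]
  d <- .stereo_table[match(dst, .stereo_table$label), ]
  bond_diff <- s$double_bond != d$double_bond
  axis_diff <- s$axis != d$axis
  dplyr::case_when(
    !bond_diff & !axis_diff ~ "NONE",
    !bond_diff & axis_diff  ~ "SBR",
    bond_diff & !axis_diff  ~ "DBI",
    TRUE                    ~ "HT"
  )
}

#' Target state reached from a source by a given motion
#'
#' Inverse of [classify_motion()]: for each source state there is exactly one
#' target per motion type.
#'
#' @param src Source state label(s).
#' @param motion Motion type(s), in `c("SBR", "DBI", "HT")`.
#' @return Character vector of target labels.
#' @export
#' @examples
#' motion_partner("B", "HT") # "C"
motion_partner <- function(src, motion) {
  check_isomer(src, "src")
  if (any(!motion %in% c("SBR", "DBI", "HT"))) {
    abort_validation("`motion` must be one of \"SBR\", \"DBI\", \"HT\".")
  }
  n <- max(length(src), length(motion))
  src <- rep_len(src, n)
  motion <- rep_len(motion, n)
  purrr::map2_chr(src, motion, function(s, m) {
    targets <- setdiff(isomer_levels(), s)
    targets[classify_motion(rep(s, 3L), targets) == m]
  })
}

#' All ordered state pairs with their motion classification
#'
#' @return A tibble with one row per ordered pair of distinct states and
#'   columns `src`, `dst`, `motion`.
#' @export
motion_pairs <- function() {
  grid <- tidyr::expand_grid(src = isomer_levels(), dst = isomer_levels())
  grid <- dplyr::filter(grid, .data$src != .data$dst)
  dplyr::mutate(grid, motion = classify_motion(.data$src, .data$dst))
}
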