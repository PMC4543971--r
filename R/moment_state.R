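# Moment-state layout and conventions.
#
# Internally all link densities use the ORDERED convention: every undirected
# link {x, y} contributes the two ordered pairs (x, y) and (y, x).  Twelve
# quantities are stored:
#   I_a, I_b                      infected node fractions per type
#   SS_aa, SS_ab, SS_bb           ordered susceptible-susceptible densities
#                                 (SS_ab is the (a,b)-ordered value, equal by
#                                 symmetry to the (b,a)-ordered value)
#   SI_aa, SI_ab, SI_ba, SI_bb    ordered pairs with the S-end listed first
#   II_aa, II_ab, II_bb           ordered infected-infected densities
# The total ordered link density is
#   SS_aa + 2 SS_ab + SS_bb + 2 (SI_aa + SI_ab + SI_ba + SI_bb)
#     + II_aa + 2 II_ab + II_bb = <k>
# so 11 of the 12 stored numbers are independent.  The literature's unordered
# convention (same-type same-state pairs counted once per link) is provided
# as an I/O view by to_paper_convention()/from_paper_convention().

MOMENT_NAMES <- c("I_a", "I_b",
                  "SS_aa", "SS_ab", "SS_bb",
                  "SI_aa", "SI_ab", "SI_ba", "SI_bb",
                  "II_aa", "II_ab", "II_bb")

# coefficient of each entry in the ordered link-density total
MOMENT_LINK_COEF <- c(I_a = 0, I_b = 0,
                      SS_aa = 1, SS_ab = 2, SS_bb = 1,
                      SI_aa = 2, SI_ab = 2, SI_ba = 2, SI_bb = 2,
                      II_aa = 1, II_ab = 2, II_bb = 1)

#' Construct a moment state
#'
#' Assembles the 12 moment variables of the pair-approximation system into a
#' named numeric vector of class `moment_state` (ordered-pair convention, see
#' Details in [to_paper_convention()]).
#'
#' @param ... the 12 components by name, or a single named numeric vector.
#' @param check validate non-negativity and names.
#' @return named numeric vector of class `moment_state`.
#' @export
moment_state <- function(..., check = TRUE) {
  args <- list(...)
  x <- if (length(args) == 1L && is.numeric(args[[1]]) &&
           length(args[[1]]) == 12L) args[[1]] else unlist(args)
  if (is.null(names(x)) && length(x) == 12L) names(x) <- MOMENT_NAMES
  if (check) {
    if (!setequal(names(x), MOMENT_NAMES))
      stop("moment state needs exactly the components: ",
           paste(MOMENT_NAMES, collapse = ", "), call. = FALSE)
    x <- x[MOMENT_NAMES]
    if (any(!is.finite(x))) stop("non-finite moment state", call. = FALSE)
  } else {
    x <- x[MOMENT_NAMES]
  }
  structure(x, class = "moment_state")
}

#' @export
print.moment_state <- function(x, digits = 6, ...) {
  cat("Moment state (ordered-pair convention)\n")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Total ordered link density of a moment state
#'
#' @param state a `moment_state`.
#' @return the ordered total, which along any valid trajectory equals the
#'   mean degree `2 K / N`.
#' @export
link_density_total <- function(state) {
  sum(MOMENT_LINK_COEF * as.numeric(state[MOMENT_NAMES]))
}

#' Convert between ordered and unordered link-density conventions
#'
#' The internal convention counts each undirected link as two ordered pairs;
#' the conventional presentation of pair approximations counts same-type
#' same-state pairs (e.g. `[S_aS_a]`) once per link and distinct-class pairs
#' (e.g. `[S_aI_b]`) once.  `to_paper_convention()` maps an internal state to
#' the unordered view (halving `SS_aa`, `SS_bb`, `II_aa`, `II_bb`);
#' `from_paper_convention()` is its exact inverse.  Node fractions are
#' unchanged.
#'
#' @param state a `moment_state` (ordered) for `to_paper_convention`; a named
#'   vector in the unordered convention for `from_paper_convention`.
#' @return the converted named vector.
#' @examples
#' s <- disease_free_state(model_params(0.03, 0.65, 0.05, 0.75, 0.002, 0.2))
#' to_paper_convention(s)[["SS_aa"]]  # 5.625 given ordered SS_aa = 11.25
#' @export
to_paper_convention <- function(state) {
  x <- as.numeric(state[MOMENT_NAMES])
  names(x) <- MOMENT_NAMES
  half <- c("SS_aa", "SS_bb", "II_aa", "II_bb")
  x[half] <- x[half] / 2
  x
}

#' @rdname to_paper_convention
#' @export
from_paper_convention <- function(state) {
  x <- as.numeric(state[MOMENT_NAMES])
  names(x) <- MOMENT_NAMES
  half <- c("SS_aa", "SS_bb", "II_aa", "II_bb")
  x[half] <- x[half] * 2
  moment_state(x)
}

#' Per-type mean degrees implied by a moment state
#'
#' The mean degree of type `u` equals the total ordered-pair density whose
#' first member has type `u`, divided by `p_u`.
#'
#' @param state a `moment_state`.
#' @param params a `sis_params`.
#' @return list with `k_a`, `k_b` and the ratio `k_b / k_a`.
#' @export
moment_degree_stats <- function(state, params) {
  s <- as.numeric(state[MOMENT_NAMES])
  names(s) <- MOMENT_NAMES
  # ordered pairs anchored on a type-a node:
  #  S_a first: SS_aa + SS_ab + SI_aa + SI_ab
  #  I_a first: II_aa + II_ab + (I_a, S_v) pairs = SI_va reversed
  deg_a <- s[["SS_aa"]] + s[["SS_ab"]] + s[["SI_aa"]] + s[["SI_ab"]] +
    s[["II_aa"]] + s[["II_ab"]] + s[["SI_aa"]] + s[["SI_ba"]]
  deg_b <- s[["SS_bb"]] + s[["SS_ab"]] + s[["SI_ba"]] + s[["SI_bb"]] +
    s[["II_bb"]] + s[["II_ab"]] + s[["SI_ab"]] + s[["SI_bb"]]
  k_a <- deg_a / params$p_a
  k_b <- deg_b / params$p_b
  list(k_a = k_a, k_b = k_b, ratio = k_b / k_a)
}

#' Swap the two type labels of a moment state
#'
#' Companion to [swap_types()]: exchanges the a/b indices of every component.
#' @param state a `moment_state`.
#' @return the relabelled `moment_state`.
#' @keywords internal
#' @export
swap_moment_types <- function(state) {
  s <- as.numeric(state[MOMENT_NAMES])
  names(s) <- MOMENT_NAMES
  moment_state(I_a = s[["I_b"]], I_b = s[["I_a"]],
               SS_aa = s[["SS_bb"]], SS_ab = s[["SS_ab"]],
               SS_bb = s[["SS_aa"]],
               SI_aa = s[["SI_bb"]], SI_ab = s[["SI_ba"]],
               SI_ba = s[["SI_ab"]], SI_bb = s[["SI_aa"]],
               II_aa = s[["II_bb"]], II_ab = s[["II_ab"]],
               II_bb = s[["II_aa"]])
}
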