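#' Particle groups and collective-variable definitions
#'
#' An `atom_group` names a set of particles (1-based indices) together with
#' their masses; a COM-distance CV is the distance between the mass-weighted
#' centers of two disjoint groups, the convention of MD engines.  This mirrors
#' how multi-domain proteins are reduced to inter-domain COM distances
#' (e.g. treating two lobes of a protein as one group each).
#'
#' @param name group label.
#' @param indices integer vector of particle indices (1-based, unique).
#' @param masses per-member masses (default all 1).
#' @return an object of class `atom_group`.
#' @export
atom_group <- function(name, indices, masses = rep(1, length(indices))) {
  indices <- as.integer(indices)
  if (anyDuplicated(indices)) stop("atom_group '", name, "': duplicate indices")
  if (any(indices < 1)) stop("atom_group '", name, "': indices are 1-based")
  stopifnot(length(masses) == length(indices), all(masses > 0))
  structure(list(name = name, indices = indices, masses = as.numeric(masses)),
            class = "atom_group")
}

#' Center-of-mass distance collective variable
#'
#' @param name CV label (e.g. `"CV_1"`).
#' @param group_a,group_b disjoint [atom_group()]s.
#' @param weighting `"mass"` (default, mass-weighted COM) or `"geometric"`
#'   (plain centroid).
#' @return an object of class `cv_definition`.
#' @export
cv_definition <- function(name, group_a, group_b, weighting = c("mass", "geometric")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(group_a, "atom_group"), inherits(group_b, "atom_group"))
  if (length(intersect(group_a$indices, group_b$indices)))
    stop("cv_definition '", name, "': groups must be disjoint")
  structure(list(name = name, type = "com_distance",
                 group_a = group_a, group_b = group_b,
                 weighting = weighting),
            class = "cv_definition")
}

#' Single-coordinate collective variable
#'
#' The position component of one particle, used as the natural CV for the
#' one-dimensional model systems (a symmetric double well needs the signed
#' coordinate, which a distance would fold).
#'
#' @param name CV label.
#' @param particle particle index (1-based).
#' @param axis coordinate axis (1-based).
#' @return an object of class `cv_definition`.
#' @export
cv_coordinate <- function(name, particle = 1L, axis = 1L) {
  structure(list(name = name, type = "coordinate",
                 particle = as.integer(particle), axis = as.integer(axis)),
            class = "cv_definition")
}

#' @export
print.cv_definition <- function(x, ...) {
  if (x$type == "coordinate")
    cat(sprintf("<cv '%s'> coordinate of particle %d, axis %d\n",
                x$name, x$particle, x$axis))
  else
    cat(sprintf("<cv '%s'> %s-weighted COM distance %s(%d) -- %s(%d)\n",
                x$name, x$weighting, x$group_a$name, length(x$group_a$indices),
                x$group_b$name, length(x$group_b$indices)))
  invisible(x)
}

group_weights <- function(g, weighting) {
  if (weighting == "geometric") rep(1 / length(g$indices), length(g$indices))
  else g$masses / sum(g$masses)
}

# internal representation consumed by the compiled core
cv_to_cpp <- function(cv) {
  if (cv$type == "coordinate")
    list(type = "coordinate", particle = cv$particle, axis = cv$axis)
  else
    list(type = "com_distance",
         ia = cv$group_a$indices, wa = group_weights(cv$group_a, cv$weighting),
         ib = cv$group_b$indices, wb = group_weights(cv$group_b, cv$weighting))
}

#' Evaluate a collective variable
#'
#' For a COM-distance CV returns \eqn{|COM_a - COM_b|} with mass-weighted
#' centers (non-negative; coincident centers legally give 0).  For a
#' coordinate CV returns the signed position component.
#'
#' @param coordinates `n x dim` coordinate matrix.
#' @param cv a [cv_definition()].
#' @return scalar CV value.
#' @export
compute_cv <- function(coordinates, cv) {
  coordinates <- as.matrix(coordinates)
  if (cv$type == "coordinate") {
    check_indices(cv$particle, nrow(coordinates), cv$name)
    return(coordinates[cv$particle, cv$axis])
  }
  check_indices(c(cv$group_a$indices, cv$group_b$indices),
                nrow(coordinates), cv$name)
  wa <- group_weights(cv$group_a, cv$weighting)
  wb <- group_weights(cv$group_b, cv$weighting)
  coma <- colSums(coordinates[cv$group_a$indices, , drop = FALSE] * wa)
  comb <- colSums(coordinates[cv$group_b$indices, , drop = FALSE] * wb)
  sqrt(sum((coma - comb)^2))
}

check_indices <- function(idx, n, name) {
  if (any(idx > n))
    stop("cv '", name, "': particle index out of range (system has ", n,
         " particles)")
}

#' Gradient of a collective variable with respect to all coordinates
#'
#' For a COM distance \eqn{d}, members of group a receive
#' \eqn{(m_i/M_a) (COM_a - COM_b)/d} (group b sign-flipped with its own mass
#' fractions); all other particles have exactly zero gradient.  Below
#' `tolerance` the geometry is singular (the direction is undefined): the
#' returned matrix is all zero and carries attribute `singular = TRUE`, which
#' callers use to drop that CV's force for the step.
#'
#' @param coordinates `n x dim` coordinate matrix.
#' @param cv a [cv_definition()].
#' @param tolerance smallest distance considered non-singular.
#' @return `n x dim` gradient matrix (attribute `singular` set when the CV is
#'   degenerate).
#' @export
cv_gradient <- function(coordinates, cv, tolerance = 1e-8) {
  coordinates <- as.matrix(coordinates)
  g <- matrix(0, nrow(coordinates), ncol(coordinates))
  if (cv$type == "coordinate") {
    check_indices(cv$particle, nrow(coordinates), cv$name)
    g[cv$particle, cv$axis] <- 1
    return(g)
  }
  d <- compute_cv(coordinates, cv)
  if (d < tolerance) {
    attr(g, "singular") <- TRUE
    return(g)
  }
  wa <- group_weights(cv$group_a, cv$weighting)
  wb <- group_weights(cv$group_b, cv$weighting)
  coma <- colSums(coordinates[cv$group_a$indices, , drop = FALSE] * wa)
  comb <- colSums(coordinates[cv$group_b$indices, , drop = FALSE] * wb)
  unit <- (coma - comb) / d
  g[cv$group_a$indices, ] <- outer(wa, unit)
  g[cv$group_b$indices, ] <- -outer(wb, unit)
  g
}

#' Evaluate several CVs at once
#'
#' @param coordinates `n x dim` matrix.
#' @param cvs list of [cv_definition()]s.
#' @return named numeric vector of CV values.
#' @export
compute_cvs <- function(coordinates, cvs) {
  setNames(vapply(cvs, function(cv) compute_cv(coordinates, cv), 0),
           vapply(cvs, `[[`, "", "name"))
}
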