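#' Symmetry operators
#'
#' A space-group operator acts on fractional coordinates as
#' `x' = R x + t` with `R` an integer-like 3x3 rotation matrix in the
#' fractional basis and `t` a fractional translation. Operators are held in
#' the order of the space-group table; the identity is always operator 1,
#' matching the `A_1`-style node labels of the lattice graph.
#'
#' @param op_id 1-based index into the operator list.
#' @param rot 3x3 rotation matrix (fractional basis).
#' @param trans fractional translation 3-vector.
#' @return An object of class `symop`.
#' @export
symop <- function(op_id, rot, trans = c(0, 0, 0)) {
  stopifnot(is.matrix(rot), all(dim(rot) == c(3, 3)), length(trans) == 3)
  structure(list(op_id = as.integer(op_id), rot = rot,
                 trans = as.numeric(trans)), class = "symop")
}

#' @export
print.symop <- function(x, ...) {
  cat(sprintf("<symop %d> %s\n", x$op_id, symop_to_xyz(x)))
  invisible(x)
}

#' Parse an xyz operator triplet
#'
#' Parses strings of the International-Tables form `"-y,x-y,z+1/3"` into a
#' rotation matrix and translation vector.
#'
#' @param s Operator triplet string.
#' @param op_id Operator index to record.
#' @return A `symop`.
#' @export
parse_symop <- function(s, op_id = NA_integer_) {
  parts <- strsplit(gsub("[[:space:]]", "", s), ",", fixed = TRUE)[[1]]
  if (length(parts) != 3)
    stop("operator triplet must have 3 comma-separated components: ", s)
  rot <- matrix(0, 3, 3)
  trans <- numeric(3)
  for (i in 1:3) {
    comp <- .parse_symop_component(parts[i], s)
    rot[i, ] <- comp$row
    trans[i] <- comp$t
  }
  symop(op_id, rot, trans)
}

.parse_symop_component <- function(p, full) {
  # tokenize into signed terms: x/y/z or numeric fractions
  row <- numeric(3); t <- 0
  # insert '+' before unsigned leading term for uniform splitting
  if (!grepl("^[+-]", p)) p <- paste0("+", p)
  terms <- regmatches(p, gregexpr("[+-][^+-]+", p))[[1]]
  if (length(terms) == 0) stop("cannot parse operator component in: ", full)
  for (tm in terms) {
    sign <- if (substr(tm, 1, 1) == "-") -1 else 1
    body <- substring(tm, 2)
    if (body %in% c("x", "y", "z")) {
      row[match(body, c("x", "y", "z"))] <- row[match(body, c("x", "y", "z"))] + sign
    } else if (grepl("^[0-9]+/[0-9]+$", body)) {
      nd <- as.numeric(strsplit(body, "/", fixed = TRUE)[[1]])
      t <- t + sign * nd[1] / nd[2]
    } else if (grepl("^[0-9.]+$", body)) {
      t <- t + sign * as.numeric(body)
    } else if (grepl("^[0-9]+/[0-9]+[xyz]$", body) || grepl("^[0-9.]+[xyz]$", body)) {
      stop("non-integer rotation coefficients are not supported: ", full)
    } else {
      stop("cannot parse operator term '", tm, "' in: ", full)
    }
  }
  list(row = row, t = t)
}

#' Render a symmetry operator as an xyz triplet string
#'
#' @param op A `symop`.
#' @return A string such as `"-x,y+1/2,-z"`.
#' @export
symop_to_xyz <- function(op) {
  axes <- c("x", "y", "z")
  comps <- character(3)
  for (i in 1:3) {
    s <- ""
    for (j in 1:3) {
      cij <- op$rot[i, j]
      if (abs(cij) > 1e-9) {
        sgn <- if (cij < 0) "-" else if (nzchar(s)) "+" else ""
        coef <- if (abs(abs(cij) - 1) < 1e-9) "" else as.character(abs(cij))
        s <- paste0(s, sgn, coef, axes[j])
      }
    }
    tr <- op$trans[i] %% 1
    if (abs(tr) > 1e-9 && abs(tr - 1) > 1e-9) {
      fr <- .as_fraction(tr)
      s <- paste0(s, "+", fr)
    }
    comps[i] <- s
  }
  paste(comps, collapse = ",")
}

.as_fraction <- function(x, denoms = c(2, 3, 4, 6, 12)) {
  for (d in denoms) {
    n <- round(x * d)
    if (abs(x - n / d) < 1e-6) return(paste0(n, "/", d))
  }
  format(x)
}

#' Compose two symmetry operators
#'
#' Returns the operator `a o b` (apply `b` first): rotation `Ra Rb`,
#' translation `Ra tb + ta`.
#'
#' @param a,b `symop` objects.
#' @return A `symop` with `op_id = NA` (not yet resolved against a group).
#' @export
symop_compose <- function(a, b) {
  symop(NA_integer_, a$rot %*% b$rot, as.numeric(a$rot %*% b$trans) + a$trans)
}

#' Invert a symmetry operator
#'
#' @param op A `symop`.
#' @return The inverse operator, `op_id = NA`.
#' @export
symop_invert <- function(op) {
  rinv <- solve(op$rot)
  symop(NA_integer_, rinv, -as.numeric(rinv %*% op$trans))
}

#' Locate an operator in a space-group list modulo lattice translations
#'
#' Finds the group operator with the same rotation whose translation differs
#' from `op`'s by an integer vector, and returns its index together with
#' that integer lattice shift.
#'
#' @param op A `symop` (e.g. a composition result).
#' @param ops List of group `symop`s.
#' @param tol Numeric tolerance.
#' @return `list(op_id =, shift = integer 3-vector)`.
#' @export
symop_match <- function(op, ops, tol = 1e-6) {
  for (g in ops) {
    if (max(abs(op$rot - g$rot)) < tol) {
      d <- op$trans - g$trans
      if (max(abs(d - round(d))) < tol) {
        return(list(op_id = g$op_id, shift = as.integer(round(d))))
      }
    }
  }
  stop("operator does not belong to the group (composition left the group)")
}
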