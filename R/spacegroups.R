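# Space-group operator table.
#
# Operator triplets (International Tables settings) for the space groups
# most common in protein crystallography, keyed by Hermann-Mauguin symbol.
# Chiral (Sohncke) groups only: protein crystals admit no improper
# operations. mmCIF inputs carrying explicit _symmetry_equiv /
# _space_group_symop loops bypass this table entirely, so any group can be
# read from a file that spells out its operators.

.SG_TABLE <- c(
  "P 1" = "x,y,z",
  "P 2" = "x,y,z;-x,y,-z",
  "P 21" = "x,y,z;-x,y+1/2,-z",
  "C 2" = "x,y,z;-x,y,-z;x+1/2,y+1/2,z;-x+1/2,y+1/2,-z",
  "P 2 2 2" = "x,y,z;-x,-y,z;x,-y,-z;-x,y,-z",
  "P 21 21 21" = "x,y,z;-x+1/2,-y,z+1/2;x+1/2,-y+1/2,-z;-x,y+1/2,-z+1/2",
  "P 21 21 2" = "x,y,z;-x,-y,z;x+1/2,-y+1/2,-z;-x+1/2,y+1/2,-z",
  "C 2 2 21" = "x,y,z;-x,-y,z+1/2;x,-y,-z;-x,y,-z+1/2;x+1/2,y+1/2,z;-x+1/2,-y+1/2,z+1/2;x+1/2,-y+1/2,-z;-x+1/2,y+1/2,-z+1/2",
  "P 4" = "x,y,z;-y,x,z;-x,-y,z;y,-x,z",
  "P 41" = "x,y,z;-y,x,z+1/4;-x,-y,z+1/2;y,-x,z+3/4",
  "P 42" = "x,y,z;-y,x,z+1/2;-x,-y,z;y,-x,z+1/2",
  "P 43" = "x,y,z;-y,x,z+3/4;-x,-y,z+1/2;y,-x,z+1/4",
  "P 4 21 2" = "x,y,z;-y+1/2,x+1/2,z;-x,-y,z;y+1/2,-x+1/2,z;x+1/2,-y+1/2,-z;-y,-x,-z;-x+1/2,y+1/2,-z;y,x,-z",
  "P 41 21 2" = "x,y,z;-y+1/2,x+1/2,z+1/4;-x,-y,z+1/2;y+1/2,-x+1/2,z+3/4;x+1/2,-y+1/2,-z+3/4;-y,-x,-z+1/2;-x+1/2,y+1/2,-z+1/4;y,x,-z",
  "P 43 21 2" = "x,y,z;-y+1/2,x+1/2,z+3/4;-x,-y,z+1/2;y+1/2,-x+1/2,z+1/4;x+1/2,-y+1/2,-z+1/4;-y,-x,-z+1/2;-x+1/2,y+1/2,-z+3/4;y,x,-z",
  "I 4" = "x,y,z;-y,x,z;-x,-y,z;y,-x,z;x+1/2,y+1/2,z+1/2;-y+1/2,x+1/2,z+1/2;-x+1/2,-y+1/2,z+1/2;y+1/2,-x+1/2,z+1/2",
  "P 3" = "x,y,z;-y,x-y,z;-x+y,-x,z",
  "P 31" = "x,y,z;-y,x-y,z+1/3;-x+y,-x,z+2/3",
  "P 32" = "x,y,z;-y,x-y,z+2/3;-x+y,-x,z+1/3",
  "P 3 1 2" = "x,y,z;-y,x-y,z;-x+y,-x,z;-y,-x,-z;-x+y,y,-z;x,x-y,-z",
  "P 3 2 1" = "x,y,z;-y,x-y,z;-x+y,-x,z;y,x,-z;x-y,-y,-z;-x,-x+y,-z",
  "P 31 2 1" = "x,y,z;-y,x-y,z+1/3;-x+y,-x,z+2/3;y,x,-z;x-y,-y,-z+2/3;-x,-x+y,-z+1/3",
  "P 32 2 1" = "x,y,z;-y,x-y,z+2/3;-x+y,-x,z+1/3;y,x,-z;x-y,-y,-z+1/3;-x,-x+y,-z+2/3",
  "R 3" = "x,y,z;-y,x-y,z;-x+y,-x,z;x+2/3,y+1/3,z+1/3;-y+2/3,x-y+1/3,z+1/3;-x+y+2/3,-x+1/3,z+1/3;x+1/3,y+2/3,z+2/3;-y+1/3,x-y+2/3,z+2/3;-x+y+1/3,-x+2/3,z+2/3",
  "R 3 2" = "x,y,z;-y,x-y,z;-x+y,-x,z;y,x,-z;x-y,-y,-z;-x,-x+y,-z;x+2/3,y+1/3,z+1/3;-y+2/3,x-y+1/3,z+1/3;-x+y+2/3,-x+1/3,z+1/3;y+2/3,x+1/3,-z+1/3;x-y+2/3,-y+1/3,-z+1/3;-x+2/3,-x+y+1/3,-z+1/3;x+1/3,y+2/3,z+2/3;-y+1/3,x-y+2/3,z+2/3;-x+y+1/3,-x+2/3,z+2/3;y+1/3,x+2/3,-z+2/3;x-y+1/3,-y+2/3,-z+2/3;-x+1/3,-x+y+2/3,-z+2/3",
  "P 6" = "x,y,z;x-y,x,z;-y,x-y,z;-x,-y,z;-x+y,-x,z;y,-x+y,z",
  "P 61" = "x,y,z;x-y,x,z+1/6;-y,x-y,z+1/3;-x,-y,z+1/2;-x+y,-x,z+2/3;y,-x+y,z+5/6",
  "P 65" = "x,y,z;x-y,x,z+5/6;-y,x-y,z+2/3;-x,-y,z+1/2;-x+y,-x,z+1/3;y,-x+y,z+1/6",
  "P 62" = "x,y,z;x-y,x,z+1/3;-y,x-y,z+2/3;-x,-y,z;-x+y,-x,z+1/3;y,-x+y,z+2/3",
  "P 64" = "x,y,z;x-y,x,z+2/3;-y,x-y,z+1/3;-x,-y,z;-x+y,-x,z+2/3;y,-x+y,z+1/3",
  "P 63" = "x,y,z;x-y,x,z+1/2;-y,x-y,z;-x,-y,z+1/2;-x+y,-x,z;y,-x+y,z+1/2",
  "P 6 2 2" = "x,y,z;x-y,x,z;-y,x-y,z;-x,-y,z;-x+y,-x,z;y,-x+y,z;-y,-x,-z;-x,-x+y,-z;-x+y,y,-z;y,x,-z;x,x-y,-z;x-y,-y,-z",
  "P 61 2 2" = "x,y,z;x-y,x,z+1/6;-y,x-y,z+1/3;-x,-y,z+1/2;-x+y,-x,z+2/3;y,-x+y,z+5/6;-y,-x,-z+5/6;-x,-x+y,-z+2/3;-x+y,y,-z+1/2;y,x,-z+1/3;x,x-y,-z+1/6;x-y,-y,-z",
  "P 65 2 2" = "x,y,z;x-y,x,z+5/6;-y,x-y,z+2/3;-x,-y,z+1/2;-x+y,-x,z+1/3;y,-x+y,z+1/6;-y,-x,-z+1/6;-x,-x+y,-z+1/3;-x+y,y,-z+1/2;y,x,-z+2/3;x,x-y,-z+5/6;x-y,-y,-z",
  "P 2 3" = "x,y,z;-x,-y,z;x,-y,-z;-x,y,-z;z,x,y;z,-x,-y;-z,x,-y;-z,-x,y;y,z,x;-y,z,-x;-y,-z,x;y,-z,-x",
  "P 21 3" = "x,y,z;-x+1/2,-y,z+1/2;x+1/2,-y+1/2,-z;-x,y+1/2,-z+1/2;z,x,y;z+1/2,-x+1/2,-y;-z,x+1/2,-y+1/2;-z+1/2,-x,y+1/2;y,z,x;-y,z+1/2,-x+1/2;-y+1/2,-z,x+1/2;y+1/2,-z+1/2,-x",
  "I 2 3" = "x,y,z;-x,-y,z;x,-y,-z;-x,y,-z;z,x,y;z,-x,-y;-z,x,-y;-z,-x,y;y,z,x;-y,z,-x;-y,-z,x;y,-z,-x;x+1/2,y+1/2,z+1/2;-x+1/2,-y+1/2,z+1/2;x+1/2,-y+1/2,-z+1/2;-x+1/2,y+1/2,-z+1/2;z+1/2,x+1/2,y+1/2;z+1/2,-x+1/2,-y+1/2;-z+1/2,x+1/2,-y+1/2;-z+1/2,-x+1/2,y+1/2;y+1/2,z+1/2,x+1/2;-y+1/2,z+1/2,-x+1/2;-y+1/2,-z+1/2,x+1/2;y+1/2,-z+1/2,-x+1/2",
  "I 21 3" = "x,y,z;-x,-y+1/2,z;x,-y,-z+1/2;-x,y+1/2,-z+1/2;z,x,y;z,-x,-y+1/2;-z+1/2,x,-y;-z+1/2,-x,y+1/2;y,z,x;-y+1/2,z,-x;-y,-z+1/2,x;y+1/2,-z+1/2,-x;x+1/2,y+1/2,z+1/2;-x+1/2,-y,z+1/2;x+1/2,-y+1/2,-z;-x+1/2,y,-z;z+1/2,x+1/2,y+1/2;z+1/2,-x+1/2,-y;-z,x+1/2,-y+1/2;-z,-x+1/2,y;y+1/2,z+1/2,x+1/2;-y,z+1/2,-x+1/2;-y+1/2,-z,x+1/2;y,-z,-x+1/2"
)

# full monoclinic symbols and spacing variants map onto table keys
.SG_ALIASES <- c(
  "P1211" = "P21", "P121" = "P2", "C121" = "C2",
  "H3" = "R3", "H32" = "R32"
)

.sg_normalize <- function(symbol) {
  s <- toupper(gsub("[[:space:]]", "", symbol))
  if (s %in% names(.SG_ALIASES)) s <- .SG_ALIASES[[s]]
  s
}

#' List of supported space-group symbols
#'
#' @return Character vector of Hermann-Mauguin symbols with built-in
#'   operator lists.
#' @export
space_group_symbols <- function() names(.SG_TABLE)

#' Resolve a Hermann-Mauguin symbol to its operator list
#'
#' @param symbol Hermann-Mauguin space-group symbol (spacing ignored, e.g.
#'   `"P 21 21 21"` or `"P212121"`).
#' @return List of `symop`, identity first (`op_id` 1).
#' @export
space_group_operators <- function(symbol) {
  key <- .sg_normalize(symbol)
  norm_keys <- vapply(names(.SG_TABLE), .sg_normalize, character(1))
  hit <- match(key, norm_keys)
  if (is.na(hit))
    stop("space group '", symbol, "' is not in the built-in table; ",
         "supply operators explicitly (mmCIF _symmetry_equiv loop)")
  trips <- strsplit(.SG_TABLE[[hit]], ";", fixed = TRUE)[[1]]
  lapply(seq_along(trips), function(i) parse_symop(trips[i], op_id = i))
}

#' Parse an explicit operator triplet list into a space-group operator set
#'
#' Used when a structure file spells out its operators. Ensures the identity
#' comes first and re-indexes operators 1..n.
#'
#' @param triplets Character vector of xyz triplets.
#' @return List of `symop`.
#' @export
operators_from_triplets <- function(triplets) {
  ops <- lapply(seq_along(triplets), function(i) parse_symop(triplets[i], i))
  is_id <- vapply(ops, function(o) {
    max(abs(o$rot - diag(3))) < 1e-9 && max(abs(o$trans %% 1)) < 1e-9
  }, logical(1))
  if (!any(is_id)) stop("operator list lacks the identity")
  ord <- order(!is_id)  # identity first, stable otherwise
  ops <- ops[ord]
  for (i in seq_along(ops)) ops[[i]]$op_id <- i
  ops
}
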