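# Minimal heavy-atom molecular graphs for the C/N/O/F group-additivity world.
# Hydrogens are never graph nodes; every atom carries an implicit-H count that
# tops its valence up exactly (C:4, N:3, O:2, F:1).

VALENCE <- c(C = 4L, N = 3L, O = 2L, F = 1L)

#' Construct a molecular graph
#'
#' A molecular graph is the universal molecule carrier of the package: heavy
#' atoms (C, N, O, F) with implicit hydrogen counts and integer-order bonds.
#' Explicit hydrogens are not represented as nodes. On construction the graph
#' is validated: connectivity, no self- or duplicate bonds, and exact valence
#' (sum of bond orders plus implicit H equals the standard valence of the
#' element).
#'
#' @param element character vector of atomic symbols, each one of
#'   `"C","N","O","F"`.
#' @param hcount integer vector of implicit hydrogen counts, one per atom. If
#'   `NULL`, hydrogen counts are computed to fill each atom's valence.
#' @param bonds a 3-column matrix (or `NULL` for no bonds) with columns
#'   `from`, `to`, `order`; atom indices are 1-based, order in `1:3`.
#' @param validate if `FALSE`, skip the valence/connectivity checks. Used
#'   internally for featurization views (see [corrupt_elements()]), never for
#'   real molecules.
#' @return an object of class `molgraph` with fields `element`, `hcount`,
#'   `bond_i`, `bond_j`, `bond_order`.
#' @examples
#' ethanol <- molgraph(c("C", "C", "O"),
#'                     bonds = cbind(c(1, 2), c(2, 3), c(1, 1)))
#' ethanol$hcount  # 3 2 1
#' @export
molgraph <- function(element, hcount = NULL, bonds = NULL, validate = TRUE) {
  element <- as.character(element)
  n <- length(element)
  if (n == 0L) stop("molgraph needs at least one atom")
  if (!all(element %in% names(VALENCE))) {
    bad <- setdiff(unique(element), names(VALENCE))
    stop("unsupported element(s): ", paste(bad, collapse = ", "))
  }
  if (is.null(bonds) || NROW(bonds) == 0L) {
    bi <- integer(0); bj <- integer(0); bo <- integer(0)
  } else {
    bonds <- matrix(as.integer(as.matrix(bonds)), ncol = 3L)
    bi <- bonds[, 1L]; bj <- bonds[, 2L]; bo <- bonds[, 3L]
    swap <- bi > bj
    tmp <- bi[swap]; bi[swap] <- bj[swap]; bj[swap] <- tmp
  }
  bsum <- bond_order_sums(n, bi, bj, bo)
  if (is.null(hcount)) {
    hcount <- VALENCE[element] - bsum
    names(hcount) <- NULL
  }
  hcount <- as.integer(hcount)
  g <- structure(list(element = element, hcount = hcount,
                      bond_i = bi, bond_j = bj, bond_order = bo),
                 class = "molgraph")
  if (validate) validate_molgraph(g)
  g
}

bond_order_sums <- function(n, bi, bj, bo) {
  s <- numeric(n)
  if (length(bi)) {
    t1 <- tapply(bo, bi, sum); s[as.integer(names(t1))] <- t1
    t2 <- tapply(bo, bj, sum)
    s[as.integer(names(t2))] <- s[as.integer(names(t2))] + t2
  }
  as.integer(s)
}

#' @rdname molgraph
#' @param g a `molgraph`.
#' @export
validate_molgraph <- function(g) {
  n <- length(g$element)
  bi <- g$bond_i; bj <- g$bond_j; bo <- g$bond_order
  if (length(bi)) {
    if (any(bi < 1L | bi > n | bj < 1L | bj > n))
      stop("bond refers to an atom index outside 1..", n)
    if (any(bi == bj)) stop("self-bonds are not allowed")
    if (anyDuplicated(paste(bi, bj))) stop("duplicate bonds are not allowed")
    if (!all(bo %in% 1:3)) stop("bond orders must be 1, 2 or 3")
  }
  if (any(g$hcount < 0L)) {
    a <- which(g$hcount < 0L)[1L]
    stop(sprintf("valence error: atom %d (%s) exceeds valence %d",
                 a, g$element[a], VALENCE[g$element[a]]))
  }
  bsum <- bond_order_sums(n, bi, bj, bo)
  ok <- bsum + g$hcount == VALENCE[g$element]
  if (!all(ok)) {
    a <- which(!ok)[1L]
    stop(sprintf(
      "valence error: atom %d (%s) has bond order sum %d + %dH != %d",
      a, g$element[a], bsum[a], g$hcount[a], VALENCE[g$element[a]]))
  }
  if (n > 1L) {
    seen <- logical(n); seen[1L] <- TRUE; frontier <- 1L
    adj <- adjacency_list(g)
    while (length(frontier)) {
      nxt <- unique(unlist(lapply(frontier, function(a) adj[[a]]$nbr)))
      nxt <- nxt[!seen[nxt]]
      seen[nxt] <- TRUE
      frontier <- nxt
    }
    if (!all(seen)) stop("graph is not connected")
  }
  invisible(g)
}

n_atoms <- function(g) length(g$element)

adjacency_list <- function(g) {
  n <- length(g$element)
  adj <- rep(list(list(nbr = integer(0), order = integer(0))), n)
  for (k in seq_along(g$bond_i)) {
    i <- g$bond_i[k]; j <- g$bond_j[k]; o <- g$bond_order[k]
    adj[[i]]$nbr <- c(adj[[i]]$nbr, j); adj[[i]]$order <- c(adj[[i]]$order, o)
    adj[[j]]$nbr <- c(adj[[j]]$nbr, i); adj[[j]]$order <- c(adj[[j]]$order, o)
  }
  adj
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph: %d heavy atoms, %d bonds> %s\n",
              length(x$element), length(x$bond_i),
              tryCatch(write_smiles(x), error = function(e) "")))
  invisible(x)
}

#' @export
format.molgraph <- function(x, ...) write_smiles(x)

# ---------------------------------------------------------------------------
# SMILES parsing (restricted dialect: C/N/O/F, -/=/#, branches, ring digits)

#' Parse a restricted SMILES string
#'
#' Supports the dialect needed for the synthetic C/N/O/F world: element
#' letters `C N O F`, branches `( )`, bond symbols `-`, `=`, `#`, and
#' single-digit ring closures. Aromatic lowercase atoms, charges, isotopes
#' and stereo markers are not part of the dialect and raise a parse error.
#' Implicit hydrogen counts are computed to fill each atom's valence.
#'
#' @param text a single SMILES string.
#' @return a [molgraph()].
#' @examples
#' parse_smiles("CCO")$hcount   # 3 2 1
#' parse_smiles("C1CC1")        # cyclopropane
#' @export
parse_smiles <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(text))
    stop("parse error: expected a non-empty SMILES string")
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  element <- character(0)
  bi <- integer(0); bj <- integer(0); bo <- integer(0)
  prev <- NA_integer_          # atom the next bond attaches to
  stack <- integer(0)          # branch return points
  pending <- NA_integer_       # explicit bond order waiting for an atom/digit
  rings <- list()              # digit -> list(atom, order)
  add_bond <- function(i, j, o) {
    a <- min(i, j); b <- max(i, j)
    if (a == b) stop("parse error: ring closure forms a self-bond")
    if (any(bi == a & bj == b))
      stop("parse error: duplicate bond between atoms ", a, " and ", b)
    bi <<- c(bi, a); bj <<- c(bj, b); bo <<- c(bo, o)
  }
  for (pos in seq_along(chars)) {
    ch <- chars[pos]
    if (ch %in% c("C", "N", "O", "F")) {
      element <- c(element, ch)
      idx <- length(element)
      if (!is.na(prev)) add_bond(prev, idx, if (is.na(pending)) 1L else pending)
      else if (!is.na(pending))
        stop("parse error at position ", pos, ": bond symbol without preceding atom")
      prev <- idx
      pending <- NA_integer_
    } else if (ch %in% c("-", "=", "#")) {
      if (!is.na(pending))
        stop("parse error at position ", pos, ": consecutive bond symbols")
      pending <- c("-" = 1L, "=" = 2L, "#" = 3L)[[ch]]
    } else if (ch == "(") {
      if (is.na(prev))
        stop("parse error at position ", pos, ": branch before any atom")
      if (!is.na(pending))
        stop("parse error at position ", pos, ": bond symbol before branch")
      stack <- c(stack, prev)
    } else if (ch == ")") {
      if (!length(stack))
        stop("parse error at position ", pos, ": unbalanced ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (grepl("[0-9]", ch)) {
      if (is.na(prev))
        stop("parse error at position ", pos, ": ring digit before any atom")
      key <- ch
      if (is.null(rings[[key]])) {
        rings[[key]] <- list(atom = prev, order = pending)
      } else {
        open <- rings[[key]]
        o <- if (!is.na(pending)) pending else open$order
        if (is.na(o)) o <- 1L
        if (!is.na(pending) && !is.na(open$order) && pending != open$order)
          stop("parse error at position ", pos,
               ": conflicting ring-closure bond orders")
        add_bond(open$atom, prev, o)
        rings[[key]] <- NULL
      }
      pending <- NA_integer_
    } else {
      stop("parse error at position ", pos, ": unsupported character '", ch, "'")
    }
  }
  if (length(stack)) stop("parse error: unbalanced '(' (", length(stack),
                          " branch(es) left open)")
  if (!is.na(pending)) stop("parse error: dangling bond symbol at end of input")
  open_rings <- names(rings)[!vapply(rings, is.null, logical(1))]
  if (length(open_rings))
    stop("parse error: unclosed ring closure(s): ",
         paste(open_rings, collapse = ", "))
  if (!length(element)) stop("parse error: no atoms in input")
  molgraph(element, bonds = cbind(bi, bj, bo))
}

# ---------------------------------------------------------------------------
# Canonical ranking and canonical SMILES output

# canonical ranking + string assembly live in src/canonical.cpp; generated
# molecules carry their canonical SMILES as an attribute
canonical_smiles <- function(g) {
  s <- attr(g, "smiles")
  if (!is.null(s)) return(s)
  canonical_smiles_cpp(match(g$element, names(VALENCE)) - 1L,
                       as.integer(g$hcount),
                       cbind(g$bond_i, g$bond_j, g$bond_order))
}

#' Write a canonical SMILES string
#'
#' The output is canonical: isomorphic graphs (any atom ordering) produce
#' byte-identical strings, and `parse_smiles(write_smiles(g))` is isomorphic
#' to `g`. Rings are written Kekule style with single-digit closures.
#'
#' @param g a [molgraph()].
#' @return a SMILES string.
#' @export
write_smiles <- function(g) {
  stopifnot(inherits(g, "molgraph"))
  canonical_smiles(g)
}

# ---------------------------------------------------------------------------
# Benson-style groups and circular fingerprints

#' Extract 1-bond-radius group keys
#'
#' One group per heavy atom: the central element, its implicit-H count and
#' the sorted multiset of (bond order, neighbor element) pairs. Hydrogen
#' neighbors appear only through the central H count. Keys are canonical
#' strings, invariant under atom reindexing.
#'
#' @param g a [molgraph()].
#' @return character vector of group keys, one per atom (a multiset).
#' @examples
#' extract_groups(parse_smiles("CCO"))
#' # "C;H3;1C" "C;H2;1C+1O" "O;H1;1C"
#' @export
extract_groups <- function(g) {
  group_keys_cpp(match(g$element, names(VALENCE)) - 1L,
                 as.integer(g$hcount),
                 cbind(g$bond_i, g$bond_j, g$bond_order))
}

# 31-based polynomial rolling hash mod 2^31-1; deterministic and
# platform-independent (all intermediates stay below 2^53).
poly_hash <- function(s) {
  vapply(s, function(x) {
    h <- 0
    for (v in utf8ToInt(x)) h <- (h * 31 + v) %% 2147483647
    h
  }, numeric(1), USE.NAMES = FALSE)
}

# Environment strings per atom for radii 0..radius. Radius 0 depends only on
# (element, H count, degree); radius k wraps the central radius-0 string with
# the sorted (bond order, neighbor radius-(k-1)) list.
atom_environments <- function(g, radius) {
  adj <- adjacency_list(g)
  deg <- tabulate(c(g$bond_i, g$bond_j), nbins = length(g$element))
  envs <- vector("list", radius + 1L)
  envs[[1L]] <- paste0(g$element, "/H", g$hcount, "/D", deg)
  if (radius >= 1L) {
    for (r in seq_len(radius)) {
      prev <- envs[[r]]
      envs[[r + 1L]] <- vapply(seq_along(g$element), function(i) {
        a <- adj[[i]]
        if (!length(a$nbr)) return(paste0(envs[[1L]][i], "()"))
        nb <- sort(paste0(a$order, "~", prev[a$nbr]))
        paste0(envs[[1L]][i], "(", paste(nb, collapse = ","), ")")
      }, character(1))
    }
  }
  envs
}

#' Hashed circular fingerprint
#'
#' Morgan-style circular fingerprint over the heavy-atom graph: every atom
#' environment at radii `0..radius` is rendered as a canonical string, hashed
#' with a fixed polynomial hash and folded modulo `nbits`. Deterministic
#' across runs and platforms; isomorphic graphs give identical vectors.
#'
#' @param g a [molgraph()].
#' @param radius maximum environment radius (bonds), `>= 0`.
#' @param nbits fingerprint length, `>= 1`.
#' @param counts if `TRUE`, return per-bit environment counts instead of 0/1
#'   presence bits. Counted fingerprints retain repeated-substructure
#'   multiplicity and are the featurization used by the fingerprint surrogate.
#' @return integer vector of length `nbits`.
#' @export
circular_fingerprint <- function(g, radius = 2L, nbits = 1024L,
                                 counts = FALSE) {
  stopifnot(radius >= 0L, nbits >= 1L)
  tab <- fp_fold_cpp(match(g$element, names(VALENCE)) - 1L,
                     as.integer(g$hcount),
                     cbind(g$bond_i, g$bond_j, g$bond_order),
                     as.integer(radius), as.integer(nbits))
  if (counts) tab else as.integer(tab > 0L)
}

#' Corrupt the element labels of a featurization view
#'
#' Returns a molecule view in which elements are remapped (for example
#' `c(N = "C")` makes nitrogen indistinguishable from carbon in the
#' features), while implicit-H counts are retained from the original graph.
#' The view is only for computing features (groups, fingerprints); it is
#' deliberately exempt from valence validation and must never be used as a
#' target oracle.
#'
#' @param g a [molgraph()].
#' @param element_map named character vector mapping elements to elements;
#'   must cover every element present in `g` (identity entries may be
#'   omitted).
#' @return a `molgraph` view (valence checks off, attribute `view = TRUE`).
#' @export
corrupt_elements <- function(g, element_map) {
  stopifnot(inherits(g, "molgraph"))
  el <- g$element
  full <- stats::setNames(names(VALENCE), names(VALENCE))
  full[names(element_map)] <- unname(element_map)
  if (!all(unique(el) %in% names(full)))
    stop("element_map must cover all elements present")
  out <- g
  out$element <- unname(full[el])
  attr(out, "view") <- TRUE
  out
}
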