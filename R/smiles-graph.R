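# A small molecular-graph layer over SMILES text. It exists for one purpose:
# writing alternative atom orderings of a molecule (randomized SMILES) while
# keeping tetrahedral parity ("@"/"@@") consistent. Scope is the non-aromatic
# organic subset the synthetic generator emits: elements H,B,C,N,O,F,P,S,Cl,
# Br,I, bond orders 1-3, branches, ring closures (single digit and %NN),
# bracket atoms with charge/hcount/parity. Aromatic (lowercase) atoms and
# directional bonds are rejected.

SMILES_ATOM_REGEX <- paste0(
  "\\[[^\\]]+\\]",          # bracket atom
  "|Cl|Br",                  # two-letter organic-subset elements
  "|[BCNOPSFI]",             # one-letter organic subset
  "|[bcnops]"                # aromatic (detected, then rejected downstream)
)

#' Count heavy atoms in a SMILES string
#'
#' Lexical count of atom tokens, excluding explicit hydrogens. Works on any
#' syntactically well-formed SMILES without invoking the toolkit.
#'
#' @param smiles character vector.
#' @return integer vector of heavy-atom counts.
#' @export
count_heavy_atoms <- function(smiles) {
  vapply(smiles, function(s) {
    toks <- regmatches(s, gregexpr(SMILES_ATOM_REGEX, s, perl = TRUE))[[1]]
    els <- sub("^\\[[0-9]*([A-Za-z][a-z]?).*$", "\\1", toks)
    sum(els != "H")
  }, integer(1), USE.NAMES = FALSE)
}

#' List element symbols appearing in a SMILES string
#'
#' @param smiles a single SMILES string.
#' @return character vector of unique element symbols (uppercased aromatic
#'   symbols included as their element), hydrogen included only when written
#'   explicitly.
#' @export
smiles_elements <- function(smiles) {
  stopifnot(length(smiles) == 1L)
  toks <- regmatches(smiles, gregexpr(SMILES_ATOM_REGEX, smiles, perl = TRUE))[[1]]
  els <- sub("^\\[[0-9]*([A-Za-z][a-z]?).*$", "\\1", toks)
  aromatic <- els %in% c("b", "c", "n", "o", "p", "s")
  els[aromatic] <- toupper(els[aromatic])
  unique(els)
}

# ---- parsing ---------------------------------------------------------------

empty_molgraph <- function() {
  list(element = character(0), hcount = integer(0), charge = integer(0),
       bracket = logical(0), chiral = character(0),
       bond_from = integer(0), bond_to = integer(0), bond_order = integer(0),
       # per chiral atom: neighbor ids in written order, 0L = implicit H
       stereo_ref = list())
}

parse_bracket_atom <- function(body) {
  # body excludes the surrounding []; e.g. "C@@H", "NH3+", "13CH4"
  m <- regexec("^([0-9]*)([A-Z][a-z]?|[a-z])(@@|@)?(H([0-9]*))?((\\+{1,3}|-{1,3})|([+-][0-9]+))?$",
               body)
  parts <- regmatches(body, m)[[1]]
  if (length(parts) == 0)
    stop("unsupported bracket atom: [", body, "]")
  element <- parts[3]
  if (element %in% c("b", "c", "n", "o", "p", "s"))
    stop("aromatic SMILES are not supported: [", body, "]")
  chiral <- parts[4]
  hcount <- if (nzchar(parts[5])) {
    if (nzchar(parts[6])) as.integer(parts[6]) else 1L
  } else 0L
  charge_s <- parts[7]
  charge <- 0L
  if (nzchar(charge_s)) {
    if (grepl("^[+-][0-9]+$", charge_s)) {
      charge <- as.integer(charge_s)
    } else {
      charge <- nchar(charge_s) * (if (startsWith(charge_s, "+")) 1L else -1L)
    }
  }
  list(element = element, chiral = chiral, hcount = hcount, charge = charge)
}

#' Parse a SMILES string into a molecular graph
#'
#' Supports the non-aromatic subset described in the package overview;
#' tetrahedral parity is recorded together with the neighbor order in which
#' it was written, so the graph can be re-serialized under any atom
#' renumbering without changing the encoded stereochemistry.
#'
#' @param smiles a single SMILES string.
#' @return a `molgraph` list (atoms, bonds, stereo annotations).
#' @export
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  if (grepl("[/\\\\]", smiles))
    stop("directional (cis/trans) bonds are not supported: ", smiles)
  if (grepl("\\.", smiles))
    stop("multi-fragment SMILES not supported; strip fragments first: ", smiles)
  g <- empty_molgraph()
  n <- 0L
  prev <- 0L                  # current attachment atom, 0 = none
  stack <- integer(0)         # open branch attachment points
  pending_order <- 1L
  ring_open <- list()         # digit -> list(atom, order, slot)
  # neighbor order bookkeeping for chirality: per atom, list of entries,
  # each an atom id or 0L (implicit H); ring-closure slots are patched later
  nbr <- list()

  i <- 1L
  nc <- nchar(smiles)
  add_atom <- function(info) {
    n <<- n + 1L
    g$element[n] <<- info$element
    g$hcount[n] <<- info$hcount
    g$charge[n] <<- info$charge
    g$bracket[n] <<- info$bracket
    g$chiral[n] <<- info$chiral
    nbr[[n]] <<- integer(0)
    if (prev > 0L) {
      g$bond_from <<- c(g$bond_from, prev)
      g$bond_to <<- c(g$bond_to, n)
      g$bond_order <<- c(g$bond_order, pending_order)
      nbr[[prev]] <<- c(nbr[[prev]], n)
      nbr[[n]] <<- c(nbr[[n]], prev)
    }
    # implicit bracket H sits right after the preceding-atom position
    if (info$bracket && info$hcount == 1L && nzchar(info$chiral))
      nbr[[n]] <<- c(nbr[[n]], 0L)
    pending_order <<- 1L
    prev <<- n
  }
  close_ring <- function(digit) {
    key <- as.character(digit)
    if (!is.null(ring_open[[key]])) {
      op <- ring_open[[key]]
      if (op$atom == prev) stop("ring closure to self in ", smiles)
      ord <- max(pending_order, op$order)
      g$bond_from <<- c(g$bond_from, op$atom)
      g$bond_to <<- c(g$bond_to, prev)
      g$bond_order <<- c(g$bond_order, ord)
      # patch the opener's reserved neighbor slot; append at the closer
      nbr[[op$atom]][op$slot] <<- prev
      nbr[[prev]] <<- c(nbr[[prev]], op$atom)
      ring_open[[key]] <<- NULL
    } else {
      if (prev == 0L) stop("ring digit before any atom in ", smiles)
      nbr[[prev]] <<- c(nbr[[prev]], NA_integer_)
      ring_open[[key]] <<- list(atom = prev, order = pending_order,
                                slot = length(nbr[[prev]]))
    }
    pending_order <<- 1L
  }

  while (i <= nc) {
    ch <- substr(smiles, i, i)
    if (ch == "[") {
      j <- regexpr("\\]", substr(smiles, i, nc))
      if (j < 0) stop("unclosed bracket in ", smiles)
      body <- substr(smiles, i + 1L, i + j - 2L)
      info <- parse_bracket_atom(body)
      if (info$element == "H") stop("explicit [H] atoms not supported: ", smiles)
      info$bracket <- TRUE
      add_atom(info)
      i <- i + j
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      two <- substr(smiles, i, i + 1L)
      if (two %in% c("Cl", "Br")) {
        add_atom(list(element = two, hcount = NA_integer_, charge = 0L,
                      bracket = FALSE, chiral = ""))
        i <- i + 2L
      } else {
        add_atom(list(element = ch, hcount = NA_integer_, charge = 0L,
                      bracket = FALSE, chiral = ""))
        i <- i + 1L
      }
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      stop("aromatic SMILES are not supported: ", smiles)
    } else if (ch == "(") {
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) stop("unbalanced ')' in ", smiles)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == "=") {
      pending_order <- 2L; i <- i + 1L
    } else if (ch == "#") {
      pending_order <- 3L; i <- i + 1L
    } else if (ch == "-") {
      pending_order <- 1L; i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      close_ring(ch); i <- i + 1L
    } else if (ch == "%") {
      digit <- substr(smiles, i + 1L, i + 2L)
      if (!grepl("^[0-9]{2}$", digit)) stop("bad %NN ring closure in ", smiles)
      close_ring(digit); i <- i + 3L
    } else {
      stop("unsupported SMILES character '", ch, "' in ", smiles)
    }
  }
  if (length(stack) > 0L) stop("unbalanced '(' in ", smiles)
  if (length(ring_open) > 0L) stop("unmatched ring closure in ", smiles)
  for (a in seq_len(n)) {
    if (nzchar(g$chiral[a])) {
      ref <- nbr[[a]]
      if (anyNA(ref) || length(ref) != 4L)
        stop("stereocenter without four resolved neighbors at atom ", a)
      g$stereo_ref[[as.character(a)]] <- ref
    }
  }
  g$n_atoms <- n
  class(g) <- "molgraph"
  g
}

# ---- writing ---------------------------------------------------------------

permutation_parity_even <- function(ref, written) {
  # TRUE when `written` is an even permutation of `ref`
  p <- match(written, ref)
  stopifnot(!anyNA(p), length(p) == length(ref))
  inversions <- 0L
  for (i in seq_along(p)) for (j in seq_len(i - 1L))
    if (p[j] > p[i]) inversions <- inversions + 1L
  inversions %% 2L == 0L
}

bond_symbol <- function(order) c("", "=", "#")[order]

format_atom <- function(g, a, written_nbrs) {
  el <- g$element[a]
  if (!g$bracket[a]) return(el)
  chiral <- g$chiral[a]
  if (nzchar(chiral)) {
    ref <- g$stereo_ref[[as.character(a)]]
    if (!permutation_parity_even(ref, written_nbrs))
      chiral <- if (chiral == "@") "@@" else "@"
  }
  hc <- g$hcount[a]
  hpart <- if (hc == 0L) "" else if (hc == 1L) "H" else paste0("H", hc)
  ch <- g$charge[a]
  cpart <- if (ch == 0L) ""
    else if (ch > 0L) paste(rep("+", ch), collapse = "")
    else paste(rep("-", -ch), collapse = "")
  paste0("[", el, chiral, hpart, cpart, "]")
}

#' Write a molecular graph as SMILES under a chosen atom ordering
#'
#' Serializes the graph depth-first, starting from the highest-priority atom
#' and visiting neighbors in priority order. Tetrahedral parity symbols are
#' recomputed for the new neighbor order, so any ordering yields a SMILES of
#' the same stereoisomer.
#'
#' @param g a `molgraph` from [parse_smiles()].
#' @param order integer permutation of `1:n_atoms` giving atom priority
#'   (first = start atom). Default: input order.
#' @return a SMILES string.
#' @export
write_smiles <- function(g, order = seq_len(g$n_atoms)) {
  stopifnot(inherits(g, "molgraph"), g$n_atoms >= 1L)
  stopifnot(length(order) == g$n_atoms, all(sort(order) == seq_len(g$n_atoms)))
  n <- g$n_atoms
  rank <- integer(n); rank[order] <- seq_len(n)
  adj <- vector("list", n)
  for (e in seq_along(g$bond_from)) {
    f <- g$bond_from[e]; t <- g$bond_to[e]
    adj[[f]] <- rbind(adj[[f]], c(t, g$bond_order[e]))
    adj[[t]] <- rbind(adj[[t]], c(f, g$bond_order[e]))
  }

  visited <- logical(n)
  parent <- integer(n)
  ring_partner <- vector("list", n)   # back-edge partners discovered at DFS
  children <- vector("list", n)
  dfs_order <- integer(0)
  # iterative DFS over the whole component, neighbors in `rank` order
  start <- order[1]
  stack <- list(start)
  parent[start] <- 0L
  seen_edge <- matrix(FALSE, 0, 0)
  edge_used <- new.env(hash = TRUE)
  ekey <- function(a, b) paste(min(a, b), max(a, b))
  visited[start] <- TRUE
  stack <- c(start)
  pos <- 1L
  # recursive DFS via explicit recursion (n is small)
  dfs <- function(a) {
    dfs_order <<- c(dfs_order, a)
    nbs <- adj[[a]]
    if (is.null(nbs)) return(invisible())
    ord <- order(rank[nbs[, 1]])
    for (k in ord) {
      b <- nbs[k, 1]
      if (!is.null(edge_used[[ekey(a, b)]])) next
      if (visited[b]) {
        edge_used[[ekey(a, b)]] <- TRUE
        ring_partner[[a]] <<- c(ring_partner[[a]], b)
        ring_partner[[b]] <<- c(ring_partner[[b]], a)
      } else {
        edge_used[[ekey(a, b)]] <- TRUE
        visited[b] <<- TRUE
        parent[b] <<- a
        children[[a]] <<- c(children[[a]], b)
        dfs(b)
      }
    }
  }
  dfs(start)
  if (!all(visited)) stop("disconnected molecular graph")

  # assign ring-closure digits: one per back edge, in discovery order at the
  # atom that is written first (the opener)
  write_pos <- integer(n); write_pos[dfs_order] <- seq_len(n)
  ring_digit <- new.env(hash = TRUE)
  next_digit <- 1L
  bond_order_of <- function(a, b) {
    nbs <- adj[[a]]
    nbs[match(b, nbs[, 1]), 2]
  }
  digit_token <- function(d) if (d < 10L) as.character(d) else sprintf("%%%02d", d)

  emit <- function(a) {
    par <- parent[a]
    # ring partners sorted: openers get new digits, closers reuse
    rps <- ring_partner[[a]]
    # order ring tokens deterministically: by partner write position
    if (!is.null(rps)) rps <- rps[order(write_pos[rps])]
    ring_toks <- character(0)
    ring_nbrs <- integer(0)
    for (b in rps) {
      key <- ekey(a, b)
      if (is.null(ring_digit[[key]])) {
        ring_digit[[key]] <- next_digit
        next_digit <<- next_digit + 1L
        d <- ring_digit[[key]]
        # opener carries the bond symbol only on the closing side by
        # convention; writing it on both sides is also legal - we write on
        # the closer (the later atom) below
        ring_toks <- c(ring_toks, digit_token(d))
      } else {
        d <- ring_digit[[key]]
        ring_toks <- c(ring_toks,
                       paste0(bond_symbol(bond_order_of(a, b)), digit_token(d)))
      }
      ring_nbrs <- c(ring_nbrs, b)
    }
    kids <- children[[a]]
    # written neighbor order for parity: parent, implicit H, ring partners in
    # digit order, then children in visit order
    written <- integer(0)
    if (par > 0L) written <- c(written, par)
    if (g$bracket[a] && !is.na(g$hcount[a]) && g$hcount[a] == 1L &&
        nzchar(g$chiral[a]))
      written <- c(written, 0L)
    written <- c(written, ring_nbrs, kids)
    atom_tok <- format_atom(g, a, written)
    out <- paste0(atom_tok, paste(ring_toks, collapse = ""))
    nk <- length(kids)
    if (nk > 0L) {
      parts <- vapply(seq_len(nk), function(k) {
        b <- kids[k]
        sub <- paste0(bond_symbol(bond_order_of(a, b)), emit(b))
        if (k < nk) paste0("(", sub, ")") else sub
      }, character(1))
      out <- paste0(out, paste(parts, collapse = ""))
    }
    out
  }
  emit(start)
}

#' Generate a randomized SMILES by atom renumbering
#'
#' Parses the input, draws a uniformly random atom permutation, and rewrites
#' the molecule starting from the new first atom. The result canonicalizes
#' back to the same molecule (same stereoisomer).
#'
#' @param canonical a valid SMILES string (non-aromatic subset).
#' @return a SMILES string for the same molecule.
#' @export
randomize_smiles <- function(canonical) {
  g <- parse_smiles(canonical)
  if (g$n_atoms == 1L) return(write_smiles(g))
  write_smiles(g, order = sample.int(g$n_atoms))
}
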