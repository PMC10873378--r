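# Synthetic molecule corpora. Molecules are grown as random acyclic or
# monocyclic graphs over a configurable element set, with an optional forced
# tetrahedral stereocenter (a carbon bearing four structurally distinct
# substituents). The generator controls corpus size, heavy-atom range, the
# fraction of chiral molecules and the "@" vs "@@" parity balance, which is
# everything the downstream training/evaluation stages are sensitive to.

STANDARD_VALENCE <- c(B = 3L, C = 4L, N = 3L, O = 2L, F = 1L, P = 3L,
                      S = 2L, Cl = 1L, Br = 1L, I = 1L)

# sample one element of x; safe for length-1 numeric vectors, where
# base::sample() would instead draw from 1:x
sample1 <- function(x) x[[sample.int(length(x), 1L)]]

# relative element abundance for achiral skeleton growth (carbon-rich,
# heteroatoms sprinkled, halogens rare and terminal)
ELEMENT_WEIGHT <- c(C = 0.70, N = 0.09, O = 0.12, S = 0.02, P = 0.005,
                    B = 0.005, F = 0.02, Cl = 0.02, Br = 0.01, I = 0.01)

# substituent library for stereocenters; attachment is at the first atom,
# entries are pairwise structurally distinct
CHIRAL_FRAGMENTS <- c("C", "N", "O", "F", "Cl", "Br", "I",
                      "CC", "CO", "CN", "OC", "NC", "CF",
                      "CCC", "C(C)C", "CCO", "CCN", "C(=O)O", "C=O",
                      "CCCC", "C(C)(C)C", "CCOC", "C(F)(F)F", "OCC", "SC")

#' Configuration for the synthetic molecule generator
#'
#' @param n_molecules number of molecules to generate.
#' @param heavy_atom_range inclusive `c(low, high)` bounds on heavy atoms
#'   (non-hydrogen); must lie within \[1, 200\].
#' @param chiral_fraction target fraction of molecules carrying at least one
#'   tetrahedral stereocenter, in \[0, 1\].
#' @param at_at_balance target fraction of assigned parities that are `"@@"`,
#'   in \[0, 1\].
#' @param element_set allowed heavy elements.
#' @param ring_prob probability that an achiral molecule is grown around a
#'   5- or 6-membered carbocycle.
#' @param chain_bias probability that skeleton growth extends the most
#'   recently added atom rather than a uniformly chosen open atom; high
#'   values give chain-like (sparsely branched) molecules.
#' @param stereocenter_range inclusive bounds on the number of tetrahedral
#'   centers a chiral molecule carries (default one; multi-center molecules
#'   are built on a chain backbone).
#' @param seed integer seed making [generate_corpus()] reproducible.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_molecules,
                             heavy_atom_range = c(3L, 50L),
                             chiral_fraction = 0.3,
                             at_at_balance = 0.5,
                             element_set = c("B", "C", "N", "O", "F", "P",
                                             "S", "Cl", "Br", "I"),
                             ring_prob = 0.3,
                             chain_bias = 0,
                             stereocenter_range = c(1L, 1L),
                             seed = 1L) {
  stopifnot(is.numeric(n_molecules), n_molecules >= 0,
            length(heavy_atom_range) == 2,
            heavy_atom_range[1] >= 1, heavy_atom_range[2] <= 200,
            heavy_atom_range[1] <= heavy_atom_range[2],
            chiral_fraction >= 0, chiral_fraction <= 1,
            at_at_balance >= 0, at_at_balance <= 1,
            all(element_set %in% names(STANDARD_VALENCE)),
            "C" %in% element_set,
            chain_bias >= 0, chain_bias <= 1,
            length(stereocenter_range) == 2,
            stereocenter_range[1] >= 1,
            stereocenter_range[1] <= stereocenter_range[2])
  structure(list(n_molecules = as.integer(n_molecules),
                 heavy_atom_range = as.integer(heavy_atom_range),
                 chiral_fraction = chiral_fraction,
                 at_at_balance = at_at_balance,
                 element_set = element_set,
                 ring_prob = ring_prob,
                 chain_bias = chain_bias,
                 stereocenter_range = as.integer(stereocenter_range),
                 seed = as.integer(seed)),
            class = "generator_config")
}

new_molgraph <- function() {
  g <- empty_molgraph()
  g$n_atoms <- 0L
  class(g) <- "molgraph"
  g
}

mg_add_atom <- function(g, element, bracket = FALSE, hcount = NA_integer_,
                        chiral = "") {
  g$n_atoms <- g$n_atoms + 1L
  n <- g$n_atoms
  g$element[n] <- element
  g$hcount[n] <- hcount
  g$charge[n] <- 0L
  g$bracket[n] <- bracket
  g$chiral[n] <- chiral
  g
}

mg_add_bond <- function(g, a, b, order = 1L) {
  g$bond_from <- c(g$bond_from, a)
  g$bond_to <- c(g$bond_to, b)
  g$bond_order <- c(g$bond_order, order)
  g
}

mg_free_valence <- function(g) {
  fv <- unname(STANDARD_VALENCE[g$element])
  if (length(g$bond_from) > 0) {
    used <- rowsum(c(g$bond_order, g$bond_order),
                   group = c(g$bond_from, g$bond_to))
    idx <- as.integer(rownames(used))
    fv[idx] <- fv[idx] - used[, 1]
  }
  fv
}

sample_element <- function(element_set, terminal_ok = TRUE) {
  w <- ELEMENT_WEIGHT[element_set]
  if (!terminal_ok) {
    keep <- STANDARD_VALENCE[element_set] >= 2
    w <- w[keep]
  }
  if (length(w) == 0) stop("element set has no polyvalent element")
  sample(names(w), 1L, prob = w)
}

# grow an achiral tree / monocycle with n heavy atoms
grow_skeleton <- function(n, element_set, ring_prob, chain_bias = 0) {
  g <- new_molgraph()
  ring <- n >= 5 && runif(1) < ring_prob
  if (ring) {
    m <- sample(5:6, 1L)
    m <- min(m, n)
    for (i in seq_len(m)) g <- mg_add_atom(g, "C")
    for (i in seq_len(m)) g <- mg_add_bond(g, i, if (i == m) 1L else i + 1L)
  } else {
    g <- mg_add_atom(g, sample_element(element_set, terminal_ok = (n == 1)))
  }
  while (g$n_atoms < n) {
    fv <- mg_free_valence(g)
    open <- which(fv >= 1)
    if (length(open) == 0) stop("skeleton ran out of free valence")
    parent <- if (length(open) == 1) open
              else if (runif(1) < chain_bias) max(open)
              else sample1(open)
    el <- sample_element(element_set, terminal_ok = TRUE)
    # avoid capping growth too early: keep at least one open valence slot
    if (g$n_atoms + 1L < n) {
      fv_after <- fv
      fv_after[parent] <- fv_after[parent] - 1
      if (sum(fv_after >= 1) == 0 && STANDARD_VALENCE[el] < 2)
        el <- sample_element(element_set, terminal_ok = FALSE)
    }
    g <- mg_add_atom(g, el)
    order <- 1L
    # occasional carbonyl: C with >=2 free valence gaining a terminal O
    if (el == "O" && g$element[parent] == "C" && fv[parent] >= 2 &&
        g$n_atoms == n && runif(1) < 0.25)
      order <- 2L
    g <- mg_add_bond(g, parent, g$n_atoms, order)
  }
  g
}

# graft a fragment (SMILES, attachment at first atom) onto atom `at`
mg_graft <- function(g, frag_smiles, at) {
  fg <- parse_smiles(frag_smiles)
  off <- g$n_atoms
  for (i in seq_len(fg$n_atoms)) {
    g <- mg_add_atom(g, fg$element[i], fg$bracket[i], fg$hcount[i],
                     fg$chiral[i])
  }
  for (e in seq_along(fg$bond_from)) {
    g <- mg_add_bond(g, fg$bond_from[e] + off, fg$bond_to[e] + off,
                     fg$bond_order[e])
  }
  mg_add_bond(g, at, off + 1L)
}

# extend the subtree rooted in the fragment starting at atom index `root`
# by `extra` additional atoms (single bonds, tree growth)
mg_extend <- function(g, member_idx, extra, element_set, chain_bias = 0) {
  for (k in seq_len(extra)) {
    fv <- mg_free_valence(g)
    open <- intersect(which(fv >= 1), member_idx)
    if (length(open) == 0) break
    parent <- if (length(open) == 1) open
              else if (runif(1) < chain_bias) max(open)
              else sample1(open)
    el <- sample_element(element_set, terminal_ok = TRUE)
    if (k < extra && STANDARD_VALENCE[el] < 2) {
      fv_after <- fv
      fv_after[parent] <- fv_after[parent] - 1
      if (length(intersect(which(fv_after >= 1), member_idx)) == 0)
        el <- sample_element(element_set, terminal_ok = FALSE)
    }
    g <- mg_add_atom(g, el)
    g <- mg_add_bond(g, parent, g$n_atoms)
    member_idx <- c(member_idx, g$n_atoms)
  }
  g
}

# one chiral molecule: a carbon center with four structurally distinct
# substituents (one may be the implicit hydrogen)
grow_chiral <- function(n, element_set, at_at_balance, chain_bias = 0) {
  frags <- CHIRAL_FRAGMENTS[vapply(CHIRAL_FRAGMENTS, function(f)
    all(smiles_elements(f) %in% element_set), logical(1))]
  sizes <- count_heavy_atoms(frags)
  use_h <- TRUE
  n_subst <- if (use_h) 3L else 4L
  budget <- n - 1L   # heavy atoms available for substituents
  stopifnot(budget >= 3L)
  # choose distinct fragments whose total size <= budget, smallest-first
  # feasibility guaranteed by single-atom fragments C, N, O
  pick <- character(0)
  pool <- sample(seq_along(frags))
  total <- 0L
  for (i in pool) {
    if (length(pick) == n_subst) break
    if (total + sizes[i] <= budget - (n_subst - length(pick) - 1L)) {
      pick <- c(pick, frags[i]); total <- total + sizes[i]
    }
  }
  if (length(pick) < n_subst) {
    pick <- sample(c("C", "N", "O"), n_subst)
    total <- sum(count_heavy_atoms(pick))
  }
  parity <- if (runif(1) < at_at_balance) "@@" else "@"
  g <- new_molgraph()
  g <- mg_add_atom(g, "C", bracket = TRUE, hcount = 1L, chiral = parity)
  biggest <- which.max(count_heavy_atoms(pick))
  frag_members <- vector("list", n_subst)
  for (k in seq_len(n_subst)) {
    before <- g$n_atoms
    g <- mg_graft(g, pick[k], 1L)
    frag_members[[k]] <- (before + 1L):g$n_atoms
  }
  extra <- budget - total
  if (extra > 0L)
    g <- mg_extend(g, frag_members[[biggest]], extra, element_set, chain_bias)
  # reference neighbor order: implicit H first, then substituent roots in
  # the order they were grafted
  roots <- vapply(frag_members, function(ix) ix[1], integer(1))
  g$stereo_ref[["1"]] <- c(0L, roots)
  attr(g, "parity") <- parity
  g
}

# a molecule with two linked branched stereocenters: center 1 carries an
# implicit H, two distinct small substituents and center 2's subtree; center
# 2 carries the bond back, an implicit H and two further distinct
# substituents. Branched centers keep the parity mapping under atom
# renumbering hard, unlike chain backbones where it collapses to few cases.
grow_two_center <- function(n, element_set, at_at_balance) {
  frags <- c("C", "N", "O", "CC", "CO", "CN", "OC", "NC", "CCO", "CCC",
             "C(C)C", "CCN")
  frags <- frags[vapply(frags, function(f)
    all(smiles_elements(f) %in% element_set), logical(1))]
  sizes <- count_heavy_atoms(frags)
  stopifnot(n >= 8)
  budget <- n - 2L                    # two center carbons
  # four substituents (two per center), pairwise distinct within a center
  pick_two <- function(maxsz) {
    ok <- which(sizes <= maxsz)
    i <- sample1(ok)
    ok2 <- setdiff(which(sizes <= maxsz - sizes[i]), i)
    if (length(ok2) == 0) ok2 <- setdiff(which(sizes == 1), i)
    j <- if (length(ok2) == 1) ok2 else sample1(ok2)
    c(i, j)
  }
  s12 <- pick_two(budget - 2L)        # keep >= 1 atom for each of s3, s4
  rem <- budget - sum(sizes[s12])
  s34 <- pick_two(rem)
  used <- sum(sizes[s12]) + sum(sizes[s34])
  extra <- budget - used
  p1 <- if (runif(1) < at_at_balance) "@@" else "@"
  p2 <- if (runif(1) < at_at_balance) "@@" else "@"
  g <- new_molgraph()
  g <- mg_add_atom(g, "C", bracket = TRUE, hcount = 1L, chiral = p1)
  g <- mg_add_atom(g, "C", bracket = TRUE, hcount = 1L, chiral = p2)
  g <- mg_add_bond(g, 1L, 2L)
  roots <- integer(4)
  members <- vector("list", 4)
  at <- c(1L, 1L, 2L, 2L)
  fr <- frags[c(s12, s34)]
  for (q in 1:4) {
    before <- g$n_atoms
    g <- mg_graft(g, fr[q], at[q])
    roots[q] <- before + 1L
    members[[q]] <- (before + 1L):g$n_atoms
  }
  if (extra > 0L) {
    big <- which.max(vapply(members, length, 0L))
    g <- mg_extend(g, members[[big]], extra, element_set)
  }
  g$stereo_ref[["1"]] <- c(0L, 2L, roots[1], roots[2])
  g$stereo_ref[["2"]] <- c(1L, 0L, roots[3], roots[4])
  attr(g, "parity") <- p1
  attr(g, "n_centers") <- 2L
  g
}

# a chain-backbone molecule bearing k tetrahedral centers: interior backbone
# carbons get an implicit H, one side substituent, and a parity symbol; the
# two backbone arms plus the side group are almost always structurally
# distinct, and accidental symmetry is caught downstream by canonicalization
grow_chain_chiral <- function(n, element_set, at_at_balance, k) {
  frags <- c("C", "N", "O", "F", "CC", "CO", "CN", "OC")
  frags <- frags[vapply(frags, function(f)
    all(smiles_elements(f) %in% element_set), logical(1))]
  frag_sizes <- count_heavy_atoms(frags)
  # backbone length: leave room for k side substituents of >= 1 atom
  m <- n - k
  stopifnot(m >= k + 2)
  g <- new_molgraph()
  backbone_el <- function(i) {
    if (runif(1) < 0.8) "C"
    else sample(intersect(c("N", "O"), element_set), 1)
  }
  g <- mg_add_atom(g, "C")
  for (i in 2:m) {
    el <- if (i == m) backbone_el(i) else backbone_el(i)
    g <- mg_add_atom(g, el)
    g <- mg_add_bond(g, i - 1L, i)
  }
  # candidate centers: interior backbone carbons, spaced apart
  interior <- which(g$element[seq_len(m)] == "C")
  interior <- interior[interior > 1 & interior < m]
  if (length(interior) < k) stop("backbone too short for stereocenters")
  centers <- sort(sample(interior, k))
  budget <- n - m                      # heavy atoms left for side groups
  parities <- character(k)
  for (j in seq_len(k)) {
    a <- centers[j]
    # side substituent: prefer a fragment that differs from both neighbors
    ok_sizes <- which(frag_sizes <= budget - (k - j))
    pick <- frags[sample1(ok_sizes)]
    before <- g$n_atoms
    g <- mg_graft(g, pick, a)
    budget <- budget - count_heavy_atoms(pick)
    side_root <- before + 1L
    parities[j] <- if (runif(1) < at_at_balance) "@@" else "@"
    g$bracket[a] <- TRUE
    g$hcount[a] <- 1L
    g$chiral[a] <- parities[j]
    g$stereo_ref[[as.character(a)]] <- c(a - 1L, 0L, a + 1L, side_root)
  }
  attr(g, "parity") <- parities[1]
  attr(g, "n_centers") <- k
  g
}

#' Generate one synthetic molecule
#'
#' Draws a heavy-atom count inside the configured range, grows an acyclic or
#' monocyclic skeleton (or a forced stereocenter when the chirality draw
#' demands one), serializes it, and canonicalizes with the toolkit.
#'
#' @param cfg a [generator_config()].
#' @param force_chiral override the random chirality draw (`NA` = draw).
#' @return a list: `canonical_smiles`, `generated_smiles`, `has_stereocenter`,
#'   `chiral_parity` (the assigned symbol, `""` for achiral),
#'   `n_heavy_atoms`, `smiles_length`, and the `graph`.
#' @export
generate_molecule <- function(cfg, force_chiral = NA) {
  stopifnot(inherits(cfg, "generator_config"))
  lo <- cfg$heavy_atom_range[1]; hi <- cfg$heavy_atom_range[2]
  chiral <- if (is.na(force_chiral)) runif(1) < cfg$chiral_fraction
            else isTRUE(force_chiral)
  if (chiral && hi < 5L)
    stop("heavy_atom_range upper bound < 5 cannot host a stereocenter ",
         "with four distinct substituents")
  count_chiral_tokens <- function(s)
    length(regmatches(s, gregexpr("@@|@", s, perl = TRUE))[[1]])
  for (attempt in 1:25) {
    n <- sample1(lo:hi)
    k <- 1L
    if (chiral) {
      k <- sample1(cfg$stereocenter_range[1]:cfg$stereocenter_range[2])
      if (k > 2L) k <- 2L              # two linked branched centers max
      n <- max(n, 5L, if (k > 1L) 8L else 5L)
      n <- min(n, max(hi, 8L))
    }
    g <- tryCatch(
      if (chiral && k > 1L)
        grow_two_center(n, cfg$element_set, cfg$at_at_balance)
      else if (chiral)
        grow_chiral(n, cfg$element_set, cfg$at_at_balance, cfg$chain_bias)
      else grow_skeleton(n, cfg$element_set, cfg$ring_prob, cfg$chain_bias),
      error = function(e) NULL)
    if (is.null(g)) next
    smi <- write_smiles(g)
    can <- canonicalize_smiles(smi)
    if (is.na(can)) next
    if (count_heavy_atoms(can) != n) next
    has_at <- grepl("@", can, fixed = TRUE)
    if (chiral && count_chiral_tokens(can) != k) next  # symmetry dropped one
    if (!chiral && has_at) next
    return(list(canonical_smiles = can,
                generated_smiles = smi,
                has_stereocenter = has_at,
                chiral_parity = if (chiral) attr(g, "parity") else "",
                n_stereocenters = if (chiral) k else 0L,
                n_heavy_atoms = n,
                smiles_length = nchar(can),
                graph = g))
  }
  stop("failed to generate a valid molecule after 25 attempts")
}

#' Generate a reproducible corpus of unique synthetic molecules
#'
#' Duplicate canonical SMILES are discarded and regenerated, so the corpus is
#' unique at the canonical level. Each record also carries one randomized
#' SMILES (fresh random atom renumbering).
#'
#' @param cfg a [generator_config()].
#' @param include_inchi also compute an InChI per molecule.
#' @param max_tries upper bound on total generation attempts, as a multiple
#'   of `n_molecules`.
#' @return a `data.frame` with columns `canonical_smiles`,
#'   `randomized_smiles`, `inchi`, `has_stereocenter`, `chiral_parity`,
#'   `n_heavy_atoms`, `smiles_length`.
#' @export
generate_corpus <- function(cfg, include_inchi = FALSE, max_tries = 20L) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  n <- cfg$n_molecules
  recs <- vector("list", n)
  seen <- new.env(hash = TRUE)
  got <- 0L; tries <- 0L
  while (got < n) {
    tries <- tries + 1L
    if (tries > max_tries * max(n, 1L))
      stop("could not assemble ", n, " unique molecules in ",
           tries - 1L, " attempts; widen heavy_atom_range or element_set")
    rec <- generate_molecule(cfg)
    if (!is.null(seen[[rec$canonical_smiles]])) next
    seen[[rec$canonical_smiles]] <- TRUE
    got <- got + 1L
    rec$randomized_smiles <- write_smiles(rec$graph,
                                          sample.int(rec$graph$n_atoms))
    recs[[got]] <- rec
  }
  df <- data.frame(
    canonical_smiles = vapply(recs, `[[`, character(1), "canonical_smiles"),
    randomized_smiles = vapply(recs, `[[`, character(1), "randomized_smiles"),
    inchi = rep(NA_character_, got),
    has_stereocenter = vapply(recs, `[[`, logical(1), "has_stereocenter"),
    chiral_parity = vapply(recs, `[[`, character(1), "chiral_parity"),
    n_stereocenters = vapply(recs, `[[`, integer(1), "n_stereocenters"),
    n_heavy_atoms = vapply(recs, `[[`, integer(1), "n_heavy_atoms"),
    smiles_length = vapply(recs, `[[`, integer(1), "smiles_length"),
    stringsAsFactors = FALSE
  )
  if (include_inchi && n > 0) df$inchi <- smiles_to_inchi(df$canonical_smiles)
  df
}

#' Synthetic downstream property labels
#'
#' Structure-derived stand-ins for measured molecular properties:
#' regression labels are `heavy atoms + 2 * (number of oxygens)` plus
#' Gaussian noise; classification labels indicate a stereocenter.
#'
#' @param corpus a corpus `data.frame` from [generate_corpus()].
#' @param task `"regression"` or `"classification"`.
#' @param noise_sd Gaussian noise SD for regression labels.
#' @return numeric vector (regression) or 0/1 integer vector (classification).
#' @export
synthetic_labels <- function(corpus, task = c("regression", "classification"),
                             noise_sd = 0.5) {
  task <- match.arg(task)
  if (task == "classification") return(as.integer(corpus$has_stereocenter))
  n_ox <- vapply(strsplit(corpus$canonical_smiles, ""), function(chs)
    sum(chs == "O"), numeric(1))
  corpus$n_heavy_atoms + 2 * n_ox + rnorm(nrow(corpus), 0, noise_sd)
}

#' Write a corpus to disk
#'
#' @param corpus corpus `data.frame`.
#' @param path output file.
#' @param format `"smiles"` (one canonical SMILES per line) or `"csv"`.
#' @export
write_corpus <- function(corpus, path, format = c("smiles", "csv")) {
  format <- match.arg(format)
  if (format == "smiles") {
    writeLines(corpus$canonical_smiles, path)
  } else {
    utils::write.csv(corpus, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a line-delimited SMILES file
#'
#' @param path file with one SMILES per line.
#' @return character vector (blank lines dropped).
#' @export
read_smiles_file <- function(path) {
  x <- readLines(path, warn = FALSE)
  x[nzchar(trimws(x))]
}
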