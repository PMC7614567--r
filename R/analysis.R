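#' Extract mutation events from a repertoire
#'
#' One row per (mutant, mutated position): which protein, the protein-local
#' 1-based position, and the wild-type and introduced residues.
#'
#' @param repertoire Tibble with `mutant_a`, `mutant_b` columns.
#' @param wildtype Wild-type pair `(A, B)`.
#' @return Tibble with columns `mutant`, `protein`, `position`, `wt_aa`,
#'   `mut_aa`.
#' @export
repertoire_mutations <- function(repertoire, wildtype) {
  wt_a <- as.integer(encode_sequences(as.character(wildtype[[1]]))[1, ])
  wt_b <- as.integer(encode_sequences(as.character(wildtype[[2]]))[1, ])
  one <- function(seqs, wt, protein) {
    m <- encode_sequences(seqs)
    diff <- which(m != matrix(wt, nrow(m), length(wt), byrow = TRUE),
                  arr.ind = TRUE)
    tibble::tibble(mutant = unname(diff[, 1]), protein = protein,
                   position = unname(diff[, 2]),
                   wt_aa = aa_alphabet()[wt[diff[, 2]]],
                   mut_aa = aa_alphabet()[m[diff]])
  }
  dplyr::arrange(
    dplyr::bind_rows(one(repertoire$mutant_a, wt_a, "A"),
                     one(repertoire$mutant_b, wt_b, "B")),
    .data$mutant, .data$protein, .data$position
  )
}

#' Amino acid usage enrichment of a selected repertoire
#'
#' Frequency of each introduced amino acid among the mutation events of the
#' selected repertoire, divided by the same frequency in the background
#' (pre-selection) repertoire. A ratio above 1 means the residue is enriched
#' by selection.
#'
#' @param selected,background Repertoires (tibbles with `mutant_a`,
#'   `mutant_b`).
#' @param wildtype Wild-type pair `(A, B)`.
#' @return `ois_enrichment` tibble with one row per amino acid: observed and
#'   background frequencies, `ratio` (`Inf` when the background frequency is
#'   0 with nonzero observed use; flagged undefined when both are 0).
#' @export
aa_usage_enrichment <- function(selected, background, wildtype) {
  stopifnot(nrow(selected) > 0, nrow(background) > 0)
  aas <- aa_alphabet()[1:20]
  cnt <- function(rep) {
    mut <- repertoire_mutations(rep, wildtype)
    tab <- table(factor(mut$mut_aa, levels = aas))
    as.numeric(tab) / sum(tab)
  }
  obs <- cnt(selected)
  bg <- cnt(background)
  ratio <- ifelse(bg > 0, obs / bg, ifelse(obs > 0, Inf, NA_real_))
  new_enrichment(tibble::tibble(
    aa = aas, observed = obs, background = bg,
    ratio = ratio, defined = bg > 0
  ))
}

#' Amino acid substitution enrichment (wild-type residue to introduced residue)
#'
#' As [aa_usage_enrichment()], but keyed by the ordered pair
#' (wild-type residue, introduced residue).
#'
#' @inheritParams aa_usage_enrichment
#' @return `ois_enrichment` tibble with one row per (from_aa, to_aa) pair.
#' @export
substitution_enrichment <- function(selected, background, wildtype) {
  stopifnot(nrow(selected) > 0, nrow(background) > 0)
  aas <- aa_alphabet()[1:20]
  cnt <- function(rep) {
    mut <- repertoire_mutations(rep, wildtype)
    tab <- table(factor(mut$wt_aa, levels = aas),
                 factor(mut$mut_aa, levels = aas))
    as.numeric(tab) / sum(tab)
  }
  obs <- cnt(selected)
  bg <- cnt(background)
  ratio <- ifelse(bg > 0, obs / bg, ifelse(obs > 0, Inf, NA_real_))
  new_enrichment(tibble::tibble(
    from_aa = rep(aas, times = 20), to_aa = rep(aas, each = 20),
    observed = obs, background = bg, ratio = ratio, defined = bg > 0
  ))
}

new_enrichment <- function(tbl) {
  structure(tbl, class = c("ois_enrichment", class(tbl)))
}

#' Positional enrichment of mutation events with a Fisher exact test
#'
#' Tests whether mutation events in a repertoire preferentially hit a set of
#' positions of interest (e.g. structurally defined interface columns).
#' The 2x2 table opposes observed mutation events (inside / outside the set)
#' to the availability of positions (inside / outside the set) under uniform
#' position usage, and is assessed by a two-tailed exact hypergeometric
#' (Fisher) test.
#'
#' Positions are 1-based indices in the concatenated alignment (protein B
#' positions offset by the boundary).
#'
#' @param selected Repertoire tibble.
#' @param positions_of_interest Subset of `all_positions`.
#' @param all_positions All candidate positions (concatenated indexing).
#' @param wildtype Wild-type pair `(A, B)` (used to map mutation events to
#'   concatenated positions).
#' @return One-row tibble: event counts, odds ratio and two-tailed p-value.
#' @export
position_enrichment <- function(selected, positions_of_interest,
                                all_positions, wildtype) {
  if (length(positions_of_interest) == 0L) {
    stop("empty position set", call. = FALSE)
  }
  stopifnot(all(positions_of_interest %in% all_positions))
  boundary <- nchar(as.character(wildtype[[1]]))[1]
  mut <- repertoire_mutations(selected, wildtype)
  gpos <- ifelse(mut$protein == "A", mut$position, boundary + mut$position)
  gpos <- gpos[gpos %in% all_positions]
  in_events <- sum(gpos %in% positions_of_interest)
  out_events <- length(gpos) - in_events
  n_in <- length(positions_of_interest)
  n_out <- length(all_positions) - n_in
  tab <- matrix(c(in_events, out_events, n_in, n_out), nrow = 2, byrow = TRUE)
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  tibble::tibble(
    events_in = in_events, events_out = out_events,
    positions_in = n_in, positions_out = n_out,
    odds_ratio = unname(ft$estimate), p_value = ft$p.value
  )
}

repertoire_states <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.character(x)) return(encode_sequences(x))
  if (inherits(x, "paired_msa")) return(x$states)
  encode_sequences(paste0(x$mutant_a, x$mutant_b))
}

#' PCA embedding (and optional k-means clustering) of mutant sequence space
#'
#' Sequences are one-hot encoded over the 21 alphabet states, mean-centered
#' (no scaling), and projected on the leading principal axes. Optional
#' k-means labels use a seeded initialization with multiple restarts.
#'
#' @param x Repertoire tibble, character sequence vector, state matrix or
#'   [paired_msa()].
#' @param n_components Number of principal components to keep.
#' @param k_clusters Optional number of k-means clusters.
#' @param seed Integer seed (k-means initialization).
#' @return An `ois_embedding`: `coords` tibble (`pc1..pcK` plus optional
#'   `cluster`), `explained_variance` fractions (non-increasing), and the
#'   total variance.
#' @export
pca_embed_cluster <- function(x, n_components = 2L, k_clusters = NULL,
                              seed = 1L) {
  m <- repertoire_states(x)
  if (nrow(m) < 2L) stop("need at least 2 sequences", call. = FALSE)
  L <- ncol(m)
  q <- 21L
  X <- matrix(0, nrow(m), L * q)
  X[cbind(rep(seq_len(nrow(m)), L),
          (rep(seq_len(L), each = nrow(m)) - 1L) * q + as.vector(m))] <- 1
  Xc <- scale(X, center = TRUE, scale = FALSE)
  pr <- stats::prcomp(Xc, center = FALSE, scale. = FALSE)
  rank <- sum(pr$sdev > 1e-12)
  if (n_components > length(pr$sdev)) {
    stop("n_components (", n_components, ") exceeds the feasible rank (",
         length(pr$sdev), ")", call. = FALSE)
  }
  total_var <- sum(Xc^2) / (nrow(m) - 1L)
  expl <- pr$sdev[seq_len(n_components)]^2 / total_var
  coords <- tibble::as_tibble(
    stats::setNames(as.data.frame(pr$x[, seq_len(n_components), drop = FALSE]),
                    paste0("pc", seq_len(n_components)))
  )
  clusters <- NULL
  inertia <- NA_real_
  if (!is.null(k_clusters)) {
    km <- with_local_seed(seed,
      stats::kmeans(pr$x[, seq_len(max(n_components, 2L)), drop = FALSE],
                    centers = k_clusters, nstart = 10L, iter.max = 100L))
    clusters <- km$cluster
    inertia <- km$tot.withinss
    coords$cluster <- factor(clusters)
  }
  structure(
    list(coords = coords, explained_variance = expl,
         total_variance = total_var, rank = rank,
         k_clusters = k_clusters, inertia = inertia,
         sdev = pr$sdev),
    class = "ois_embedding"
  )
}

#' @exportS3Method base::print
print.ois_embedding <- function(x, ...) {
  cat("<ois_embedding> ", nrow(x$coords), " sequences, ",
      length(x$explained_variance), " components (",
      paste(signif(100 * x$explained_variance, 3), collapse = "%, "),
      "% variance)\n", sep = "")
  invisible(x)
}

#' Within-cluster inertia across a sweep of k
#'
#' @param x As in [pca_embed_cluster()].
#' @param k_values Candidate cluster numbers.
#' @param n_components Components used for clustering.
#' @param seed Integer seed.
#' @return Tibble with `k` and total within-cluster sum of squares.
#' @export
kmeans_inertia_sweep <- function(x, k_values = 2:15, n_components = 2L,
                                 seed = 1L) {
  tibble::tibble(
    k = as.integer(k_values),
    inertia = vapply(k_values, function(k) {
      pca_embed_cluster(x, n_components = n_components, k_clusters = k,
                        seed = seed)$inertia
    }, numeric(1))
  )
}

#' Per-position mutation frequency profile (logo-ready)
#'
#' For each protein-local position and each amino acid, the fraction of
#' mutants in the repertoire carrying that substitution there. Wild-type
#' residues are excluded, so the per-position sum equals the fraction of
#' mutants mutated at that position.
#'
#' @inheritParams repertoire_mutations
#' @return Tibble `protein`, `position`, `aa`, `frequency` (nonzero rows
#'   only, completed with zero rows for never-mutated positions).
#' @export
mutation_frequency_profile <- function(repertoire, wildtype) {
  stopifnot(nrow(repertoire) > 0)
  n <- nrow(repertoire)
  mut <- repertoire_mutations(repertoire, wildtype)
  la <- nchar(as.character(wildtype[[1]]))[1]
  lb <- nchar(as.character(wildtype[[2]]))[1]
  grid <- dplyr::bind_rows(
    tidyr::expand_grid(protein = "A", position = seq_len(la),
                       aa = aa_alphabet()),
    tidyr::expand_grid(protein = "B", position = seq_len(lb),
                       aa = aa_alphabet())
  )
  counts <- dplyr::count(mut, .data$protein, .data$position,
                         aa = .data$mut_aa)
  out <- dplyr::left_join(grid, counts,
                          by = c("protein", "position", "aa"))
  out$frequency <- ifelse(is.na(out$n), 0, out$n / n)
  dplyr::select(out, -"n")
}

#' Distribution of all intragroup pairwise Hamming distances
#'
#' @param sequences Character vector, state matrix, repertoire tibble or
#'   [paired_msa()] (at least two equal-length sequences).
#' @return Tibble `distance` (0..L), `count`; the raw `n(n-1)/2` distances
#'   are attached as the `"distances"` attribute.
#' @export
pairwise_hamming_distribution <- function(sequences) {
  m <- repertoire_states(sequences)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 sequences", call. = FALSE)
  L <- ncol(m)
  q <- max(m)
  X <- matrix(0, n, L * q)
  X[cbind(rep(seq_len(n), L),
          (rep(seq_len(L), each = n) - 1L) * q + as.vector(m))] <- 1
  matches <- tcrossprod(X)
  d <- L - matches[upper.tri(matches)]
  out <- tibble::tibble(
    distance = 0:L,
    count = as.integer(table(factor(d, levels = 0:L)))
  )
  attr(out, "distances") <- as.integer(d)
  out
}

#' Interface positions of a two-protein complex
#'
#' A residue is interfacial iff some pair of heavy atoms across the two
#' proteins lies strictly closer than `cutoff` Angstrom (reference cutoff:
#' 6 Angstrom).
#'
#' @param coords_a,coords_b Data frames of heavy-atom coordinates with
#'   columns `residue`, `x`, `y`, `z` (one row per atom).
#' @param cutoff Distance threshold in Angstrom (strict inequality).
#' @return Tibble `protein` (`"A"`/`"B"`), `residue`, sorted.
#' @export
interface_positions <- function(coords_a, coords_b, cutoff = 6) {
  check <- function(d, nm) {
    if (nrow(d) == 0L || !all(c("residue", "x", "y", "z") %in% names(d)) ||
        !all(is.finite(as.matrix(d[, c("x", "y", "z")])))) {
      stop("malformed coordinates for protein ", nm,
           ": need non-empty finite columns residue, x, y, z", call. = FALSE)
    }
  }
  check(coords_a, "A"); check(coords_b, "B")
  A <- as.matrix(coords_a[, c("x", "y", "z")])
  B <- as.matrix(coords_b[, c("x", "y", "z")])
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  hit <- which(d2 < cutoff^2 - 1e-12, arr.ind = TRUE)
  res_a <- sort(unique(coords_a$residue[hit[, 1]]))
  res_b <- sort(unique(coords_b$residue[hit[, 2]]))
  dplyr::bind_rows(
    tibble::tibble(protein = "A", residue = res_a),
    tibble::tibble(protein = "B", residue = res_b)
  )
}

#' Read heavy-atom coordinates for two chains of a PDB structure
#'
#' Thin wrapper around `bio3d::read.pdb()`: extracts non-hydrogen `ATOM`
#' records for the two chains in the format expected by
#' [interface_positions()].
#'
#' @param path PDB file path.
#' @param chain_a,chain_b Chain identifiers for proteins A and B.
#' @return List with elements `a` and `b`: tibbles `residue`, `x`, `y`, `z`.
#' @export
read_structure_pair <- function(path, chain_a, chain_b) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("the bio3d package is required to read PDB files", call. = FALSE)
  }
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  heavy <- at$type == "ATOM" & !(toupper(substr(trimws(at$elety), 1, 1)) == "H")
  get <- function(ch) {
    sel <- heavy & at$chain == ch
    tibble::tibble(residue = at$resno[sel],
                   x = at$x[sel], y = at$y[sel], z = at$z[sel])
  }
  list(a = get(chain_a), b = get(chain_b))
}
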