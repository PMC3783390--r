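#' Support matrix of a model society
#'
#' A `support_matrix` bundles the binary directed support structure `C` of a
#' society with a per-occupation society label. Entry `c_ij = 1` means that
#' occupation `j` supports occupation `i`: `j`'s productivity contributes to
#' `i`'s competing strength against the environment. Labels tag each
#' occupation as belonging to the `"original"`, `"derived"` or `"invader"`
#' society, so that scenario engines can track the societies separately.
#'
#' @param C square binary (0/1) matrix.
#' @param labels character vector of society labels, one per occupation;
#'   recycled if length 1.
#' @param gen_params optional list recording the generation probabilities.
#' @return An object of class `support_matrix` with elements `C` (integer
#'   matrix), `labels` and `gen_params`.
#' @seealso [generate_support_matrix()], [generate_two_society_matrix()],
#'   [is_irreducible()]
#' @export
support_matrix <- function(C, labels = "original", gen_params = list()) {
  C <- as.matrix(C)
  if (nrow(C) != ncol(C)) stop("support matrix must be square")
  if (nrow(C) < 1L) stop("support matrix must have at least one occupation")
  if (!all(C %in% c(0, 1))) stop("support matrix entries must be 0 or 1")
  storage.mode(C) <- "integer"
  n <- nrow(C)
  if (length(labels) == 1L) labels <- rep(labels, n)
  if (length(labels) != n) stop("labels must have one entry per occupation")
  society_codes(labels)  # validates the alphabet
  structure(list(C = C, labels = labels, gen_params = gen_params),
            class = "support_matrix")
}

#' @export
as.matrix.support_matrix <- function(x, ...) x$C

#' @export
print.support_matrix <- function(x, ...) {
  n <- nrow(x$C)
  cat("<support_matrix> ", n, " occupations, ", sum(x$C), " support links\n",
      sep = "")
  tab <- table(factor(x$labels, levels = SOCIETY_LEVELS))
  tab <- tab[tab > 0]
  cat("  societies: ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of potential occupations
#' @param sm a [support_matrix()].
#' @return Integer count of rows of the support matrix.
#' @export
n_occupations <- function(sm) nrow(as_support_mat(sm))

as_support_mat <- function(C) {
  if (inherits(C, "support_matrix")) return(C$C)
  C <- as.matrix(C)
  if (nrow(C) != ncol(C)) stop("support matrix must be square")
  C
}

support_labels <- function(C, n) {
  if (inherits(C, "support_matrix")) C$labels else rep("original", n)
}

#' Test irreducibility (strong connectivity) of a support structure
#'
#' A standalone society is legal when its support digraph is irreducible:
#' every occupation is supported, directly or through intermediaries, by every
#' other occupation. Irreducibility is equivalent to strong connectivity of
#' the digraph with an edge j -> i for every `c_ij = 1`. A single occupation
#' is irreducible exactly when it supports itself (`C = [1]`).
#'
#' @param C a [support_matrix()] or a square binary matrix.
#' @return `TRUE` if the digraph is strongly connected.
#' @export
is_irreducible <- function(C) {
  M <- as_support_mat(C)
  n <- nrow(M)
  if (n == 1L) return(M[1L, 1L] == 1)
  g <- igraph::graph_from_adjacency_matrix(M != 0, mode = "directed")
  igraph::is_connected(g, mode = "strong")
}

#' Generate a random binary support matrix
#'
#' Draws each entry independently as Bernoulli(`p_c`). When
#' `require_irreducible` is set, matrices are re-drawn until the support
#' digraph is strongly connected (a legal standalone society), up to
#' `max_attempts` draws. When `ensure_self_supporter` is set and no diagonal
#' entry came out 1, one randomly chosen occupation is made self-supporting,
#' so the society always contains a valid single-occupation seed.
#'
#' @param n number of potential occupations (>= 1).
#' @param p_c support probability between each ordered pair of occupations.
#' @param seed optional integer seed for the generation.
#' @param require_irreducible re-draw until the matrix is irreducible.
#' @param ensure_self_supporter guarantee at least one diagonal 1.
#' @param max_attempts rejection-sampling cap; exceeding it signals that
#'   `p_c` is too small for `n` to yield an irreducible structure.
#' @param labels society label for all occupations (default `"original"`).
#' @return A [support_matrix()].
#' @export
generate_support_matrix <- function(n, p_c, seed = NULL,
                                    require_irreducible = TRUE,
                                    ensure_self_supporter = FALSE,
                                    max_attempts = 1000L,
                                    labels = "original") {
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  if (!is.numeric(p_c) || length(p_c) != 1L || p_c < 0 || p_c > 1)
    stop("p_c must be a probability in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  for (attempt in seq_len(max_attempts)) {
    C <- matrix(rbinom(n * n, 1L, p_c), n, n)
    if (ensure_self_supporter && all(diag(C) == 0L)) {
      k <- if (n == 1L) 1L else sample.int(n, 1L)
      C[k, k] <- 1L
    }
    sm <- support_matrix(C, labels = labels,
                         gen_params = list(n = n, p_c = p_c))
    if (!require_irreducible || is_irreducible(sm)) return(sm)
  }
  stop("failed to generate an irreducible support matrix in ", max_attempts,
       " attempts; p_c = ", p_c, " is likely too small for n = ", n)
}

#' Specification of a multi-society support structure
#'
#' Block sizes and block-wise support probabilities for a compound matrix of
#' original, derived and invader occupations. `p_c_xy` is the probability of
#' an occupation of society x supporting an occupation of society y, so it
#' fills the matrix block with rows in y and columns in x. Probabilities
#' above 1 are capped at 1 with a warning.
#'
#' @param n_o,n_d,n_i block sizes (original >= 1, others >= 0).
#' @param p_c_oo,p_c_od,p_c_do,p_c_dd,p_c_ii block-wise support
#'   probabilities.
#' @return A list of class `inter_society_spec`.
#' @export
inter_society_spec <- function(n_o, n_d = 0, n_i = 0, p_c_oo,
                               p_c_od = 0, p_c_do = 0, p_c_dd = 0,
                               p_c_ii = 0) {
  for (nm in c("n_o", "n_d", "n_i")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v != round(v))
      stop(nm, " must be a nonnegative integer")
  }
  if (n_o < 1) stop("n_o must be >= 1")
  probs <- list(p_c_oo = p_c_oo, p_c_od = p_c_od, p_c_do = p_c_do,
                p_c_dd = p_c_dd, p_c_ii = p_c_ii)
  probs <- lapply(stats::setNames(names(probs), names(probs)), function(nm) {
    cap_probability(probs[[nm]], nm)
  })
  structure(c(list(n_o = as.integer(n_o), n_d = as.integer(n_d),
                   n_i = as.integer(n_i)), probs),
            class = "inter_society_spec")
}

cap_probability <- function(p, name) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0)
    stop(name, " must be a probability in [0, 1]")
  if (p > 1) {
    warning(name, " = ", p, " exceeds 1; capped at 1")
    p <- 1
  }
  p
}

#' Generate a block-structured support matrix for interacting societies
#'
#' Builds the compound matrix for an original society plus optional derived
#' and invader blocks. The original block is drawn irreducible (a legal
#' society); the derived block is unconstrained (it need not be able to stand
#' alone); the invader block, when present, is drawn irreducible, because an
#' invading squad is an intact foreign society. Cross-blocks between original
#' and derived occupations are filled from `p_c_od` / `p_c_do`; all blocks
#' involving invaders and non-invaders are zero (pure competition through the
#' shared environment).
#'
#' @param spec an [inter_society_spec()].
#' @param seed optional integer seed.
#' @param max_attempts rejection cap for the irreducible blocks.
#' @return A [support_matrix()] with labels `original`/`derived`/`invader`.
#' @export
generate_two_society_matrix <- function(spec, seed = NULL,
                                        max_attempts = 1000L) {
  if (!inherits(spec, "inter_society_spec"))
    spec <- do.call(inter_society_spec, as.list(spec))
  if (!is.null(seed)) set.seed(seed)
  n_o <- spec$n_o; n_d <- spec$n_d; n_i <- spec$n_i
  n <- n_o + n_d + n_i
  C <- matrix(0L, n, n)
  io <- seq_len(n_o)
  id <- if (n_d > 0) n_o + seq_len(n_d) else integer(0)
  ii <- if (n_i > 0) n_o + n_d + seq_len(n_i) else integer(0)

  C[io, io] <- as.matrix(generate_support_matrix(
    n_o, spec$p_c_oo, require_irreducible = TRUE,
    max_attempts = max_attempts))
  if (n_d > 0) {
    # o supports d: rows derived, columns original (and transposed for d -> o)
    C[id, io] <- matrix(rbinom(n_d * n_o, 1L, spec$p_c_od), n_d, n_o)
    C[io, id] <- matrix(rbinom(n_o * n_d, 1L, spec$p_c_do), n_o, n_d)
    C[id, id] <- matrix(rbinom(n_d * n_d, 1L, spec$p_c_dd), n_d, n_d)
  }
  if (n_i > 0) {
    C[ii, ii] <- as.matrix(generate_support_matrix(
      n_i, spec$p_c_ii, require_irreducible = TRUE,
      max_attempts = max_attempts))
  }
  labels <- c(rep("original", n_o), rep("derived", n_d), rep("invader", n_i))
  support_matrix(C, labels = labels, gen_params = unclass(spec))
}

#' Write a support matrix to disk
#'
#' Two plain-text formats are supported: a dense adjacency CSV whose header
#' row carries the occupation ids, and a two-column edge-list TSV
#' (`supporter<TAB>supported`, one row per support link). Society labels go
#' to a companion CSV (`id,label`) when `labels_path` is given.
#'
#' @param sm a [support_matrix()].
#' @param path output file.
#' @param format `"adjacency"` or `"edgelist"`.
#' @param labels_path optional path for the labels CSV.
#' @export
write_support_matrix <- function(sm, path, format = c("adjacency", "edgelist"),
                                 labels_path = NULL) {
  format <- match.arg(format)
  M <- as_support_mat(sm)
  n <- nrow(M)
  ids <- paste0("occ_", seq_len(n))
  if (format == "adjacency") {
    df <- as.data.frame(M)
    names(df) <- ids
    write.csv(df, path, row.names = FALSE)
  } else {
    idx <- which(M == 1L, arr.ind = TRUE)
    df <- data.frame(supporter = ids[idx[, "col"]],
                     supported = ids[idx[, "row"]])
    df <- df[order(idx[, "col"], idx[, "row"]), , drop = FALSE]
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(labels_path)) {
    write.csv(data.frame(id = ids, label = support_labels(sm, n)),
              labels_path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a support matrix written by [write_support_matrix()]
#'
#' @param path adjacency CSV or edge-list TSV.
#' @param format `"adjacency"` or `"edgelist"`.
#' @param labels_path optional labels CSV; also fixes the occupation set for
#'   edge lists whose isolated occupations would otherwise be dropped.
#' @return A [support_matrix()].
#' @export
read_support_matrix <- function(path, format = c("adjacency", "edgelist"),
                                labels_path = NULL) {
  format <- match.arg(format)
  lab_df <- if (!is.null(labels_path)) read.csv(labels_path) else NULL
  if (format == "adjacency") {
    df <- read.csv(path, check.names = FALSE)
    M <- as.matrix(df)
    ids <- colnames(M)
    dimnames(M) <- NULL
  } else {
    df <- read.delim(path, stringsAsFactors = FALSE)
    ids <- unique(c(df$supporter, df$supported, lab_df$id))
    ids <- ids[order(as.integer(sub("^occ_", "", ids)))]
    n <- length(ids)
    M <- matrix(0L, n, n)
    M[cbind(match(df$supported, ids), match(df$supporter, ids))] <- 1L
  }
  labels <- if (!is.null(lab_df)) lab_df$label[match(ids, lab_df$id)]
            else "original"
  support_matrix(M, labels = labels)
}
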