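#' Pearson-correlation distance between per-sample mutation profiles
#'
#' Builds one profile vector per sample over the full mutation union —
#' allelic ratios (`mode = "vaf"`, default) or 1/0 presence calls
#' (`mode = "binary"`), with `INCONCLUSIVE` cells set to 0 — appends an
#' all-zero control profile (the aberration-free root), and returns
#' \eqn{d(i, j) = 1 - r(i, j)} for the Pearson correlation `r`. When either
#' profile has zero variance (notably the control), `r` is defined as 0 so
#' that `d = 1`: the control stays equidistant from every sample instead of
#' undefined.
#'
#' @param matrix A `presence_matrix`.
#' @param mode `"vaf"` or `"binary"`.
#' @param control Label of the appended zero profile.
#' @return Symmetric distance matrix (labels x labels) with zero diagonal.
#' @export
profile_distance_matrix <- function(matrix, mode = c("vaf", "binary"),
                                    control = "control") {
  mode <- match.arg(mode)
  if (ncol(matrix$call) < 2)
    stop("degenerate-input error: need >= 2 samples", call. = FALSE)
  if (nrow(matrix$call) < 2)
    stop("degenerate-input error: need >= 2 mutations", call. = FALSE)
  prof <- if (mode == "vaf") {
    v <- matrix$vaf
    v[is.na(v) | matrix$call == "INCONCLUSIVE"] <- 0
    v
  } else {
    (matrix$call == "PRESENT") * 1
  }
  prof <- cbind(prof, 0)
  colnames(prof)[ncol(prof)] <- control
  pearson_distance(prof)
}

# 1 - Pearson r over columns; zero-variance columns correlate 0 with
# everything (distance 1), diagonal forced to 0
pearson_distance <- function(prof) {
  n <- ncol(prof)
  sds <- apply(prof, 2, stats::sd)
  r <- suppressWarnings(stats::cor(prof))
  r[sds == 0, ] <- 0
  r[, sds == 0] <- 0
  d <- 1 - r
  diag(d) <- 0
  dimnames(d) <- list(colnames(prof), colnames(prof))
  d
}

#' Neighbour-joining tree reconstruction
#'
#' Standard Saitou-Nei agglomeration: at each step the pair of active nodes
#' minimizing the Q-criterion
#' \eqn{Q(i,j) = (m - 2) d(i,j) - r_i - r_j} is joined, branch lengths are
#' computed by the usual formulas and clamped at zero, and distances to the
#' new node follow the reduction formula. Ties in Q (within 1e-12) are
#' broken by the lexicographically smallest pair of subtree labels (each
#' subtree is labelled by its smallest leaf), making the output
#' deterministic. The tree is unrooted; when a leaf named `control` is
#' present it is recorded as the designated root/outgroup.
#'
#' @param D Symmetric distance matrix with labelled rows/columns.
#' @param control Name of the control leaf, if any.
#' @return An [ape::read.tree()] `phylo` object (unrooted) with attribute
#'   `"control"` set to the control leaf name when present.
#' @export
neighbour_joining <- function(D, control = "control") {
  D <- as.matrix(D)
  labels <- rownames(D)
  if (is.null(labels)) labels <- colnames(D)
  n <- nrow(D)
  if (n < 3) stop("trivial-tree error: need >= 3 labels", call. = FALSE)
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop("input error: distance matrix must be symmetric", call. = FALSE)
  dimnames(D) <- list(labels, labels)

  # active nodes are subtree descriptors: newick fragment + smallest leaf
  nodes <- lapply(labels, function(l) list(newick = newick_quote(l), min = l))
  while (length(nodes) > 3L) {
    m <- length(nodes)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- vapply(seq_len(nrow(cand)), function(k) {
      pair <- sort(c(nodes[[cand[k, 1]]]$min, nodes[[cand[k, 2]]]$min))
      paste(pair, collapse = "\r")
    }, character(1))
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]

    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    li <- max(li, 0); lj <- max(lj, 0)
    dnew <- (D[i, -c(i, j)] + D[j, -c(i, j)] - D[i, j]) / 2

    nodes[[i]] <- join_nodes(list(nodes[[i]], nodes[[j]]), c(li, lj))
    keep <- setdiff(seq_len(m), j)
    D <- D[keep, keep, drop = FALSE]
    inew <- which(keep == i)
    D[inew, -inew] <- D[-inew, inew] <- dnew
    nodes <- nodes[keep]
  }

  # final three-node join: star resolution with closed-form branch lengths
  d12 <- D[1, 2]; d13 <- D[1, 3]; d23 <- D[2, 3]
  lens <- pmax(c((d12 + d13 - d23) / 2,
                 (d12 + d23 - d13) / 2,
                 (d13 + d23 - d12) / 2), 0)
  root <- join_nodes(nodes, lens)
  tree <- ape::read.tree(text = paste0(root$newick, ";"))
  if (control %in% tree$tip.label) attr(tree, "control") <- control
  tree
}

# canonical join: children ordered by smallest contained leaf label
join_nodes <- function(children, lengths) {
  ord <- order(vapply(children, `[[`, character(1), "min"))
  parts <- vapply(ord, function(k) {
    sprintf("%s:%.17g", children[[k]]$newick, lengths[k])
  }, character(1))
  list(newick = paste0("(", paste(parts, collapse = ","), ")"),
       min = children[[ord[1]]]$min)
}

newick_quote <- function(x) {
  if (grepl("[ (),:;\\[\\]']", x)) paste0("'", gsub("'", "''", x), "'") else x
}

#' Serialize a tree as canonical Newick text
#'
#' Branch lengths are written with 6 significant digits. When the tree has a
#' designated control leaf it is placed as the outgroup (the tree is rooted
#' at the control's attachment edge) before writing. Sibling clades are
#' ordered by their smallest leaf label, so trees that are equal up to
#' rotation serialize identically, and output round-trips through
#' [ape::read.tree()].
#'
#' @param tree A `phylo` object, optionally with attribute `"control"`.
#' @param digits Significant digits for branch lengths.
#' @return A single Newick string (terminated by `;`).
#' @export
write_newick <- function(tree, digits = 6) {
  control <- attr(tree, "control")
  if (!is.null(control) && control %in% tree$tip.label && ape::Ntip(tree) > 3) {
    tree <- ape::root(tree, outgroup = control, resolve.root = FALSE)
  }
  paste0(canonical_newick(tree, digits = digits), ";")
}

canonical_newick <- function(tree, digits = 6) {
  n_tip <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  min_label <- function(node) {
    if (node <= n_tip) return(tree$tip.label[node])
    min(vapply(kids[[as.character(node)]],
               function(e) min_label(tree$edge[e, 2]), character(1)))
  }
  fmt <- function(node, len) {
    body <- if (node <= n_tip) {
      newick_quote(tree$tip.label[node])
    } else {
      rows <- kids[[as.character(node)]]
      ch <- tree$edge[rows, 2]
      ord <- order(vapply(ch, min_label, character(1)))
      paste0("(", paste(vapply(ord, function(k)
        fmt(ch[k], tree$edge.length[rows[k]]), character(1)),
        collapse = ","), ")")
    }
    if (is.na(len)) body
    else paste0(body, ":", sprintf("%.*g", digits, len))
  }
  fmt(n_tip + 1L, NA_real_)
}
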