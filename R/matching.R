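# Classification-based feature matching: per image, a match matrix keeps at
# most one feature per category (the one with the highest classification
# probability); left/right features of the same retained category are then
# matched. Categories are 1-based integers in this implementation.

#' Build the per-category match matrix for one image
#'
#' All entries start at zero; the classified features are traversed in order
#' and entry `i` is overwritten only when the candidate's probability is
#' strictly greater than the stored one, so exactly the per-category
#' maximum-probability feature is retained and the earliest-seen feature
#' wins exact ties.
#'
#' @param classifications data frame with columns `u`, `v` (0-based pixel
#'   position), `category` (integer in `1..n`) and `probability`.
#' @param n number of categories.
#' @return An object of class `match_matrix`: list with `n`, an `n x 2`
#'   `position` matrix and a length-`n` `probability` vector (zeros mark
#'   empty entries).
#' @export
build_match_matrix <- function(classifications, n) {
  stopifnot(is.data.frame(classifications),
            all(c("u", "v", "category", "probability") %in% names(classifications)))
  n <- as.integer(n)
  if (nrow(classifications) > 0 &&
      any(classifications$category < 1L | classifications$category > n))
    stop("category out of range 1..n")
  pos <- matrix(0, n, 2, dimnames = list(NULL, c("u", "v")))
  prob <- numeric(n)
  for (i in seq_len(nrow(classifications))) {
    ci <- classifications$category[i]
    if (classifications$probability[i] > prob[ci]) {
      prob[ci] <- classifications$probability[i]
      pos[ci, ] <- c(classifications$u[i], classifications$v[i])
    }
  }
  structure(list(n = n, position = pos, probability = prob),
            class = "match_matrix")
}

#' Match the left and right match matrices
#'
#' Exactly the categories retained (nonzero probability) in both matrices
#' contribute one match pair each.
#'
#' @param ml,mr [build_match_matrix()] results for the left and right image,
#'   built with the same `n`.
#' @return A data frame sorted by `category` with 0-based pixel columns
#'   `lu`, `lv`, `ru`, `rv` and the two retained probabilities `lprob`,
#'   `rprob`.
#' @export
compute_matches <- function(ml, mr) {
  stopifnot(inherits(ml, "match_matrix"), inherits(mr, "match_matrix"))
  if (ml$n != mr$n) stop("match matrices have different category counts")
  cats <- which(ml$probability > 0 & mr$probability > 0)
  data.frame(category = cats,
             lu = ml$position[cats, 1], lv = ml$position[cats, 2],
             ru = mr$position[cats, 1], rv = mr$position[cats, 2],
             lprob = ml$probability[cats], rprob = mr$probability[cats])
}

#' Select persistent feature categories from training frames
#'
#' Detected features are linked across consecutive frames by greedy
#' nearest-neighbour chaining within `link_radius`; chains observed in at
#' least `lambda * K` of the `K` frames become categories. This provides the
#' cross-frame identities used to label training patches.
#'
#' @param detections list of `K` data frames with columns `u`, `v` (one per
#'   frame, in frame order).
#' @param lambda persistence threshold as a fraction of frames, in `(0, 1]`.
#' @param link_radius maximum pixel distance linking a detection to a chain.
#' @return A data frame with one row per category: `category` (stable
#'   1-based label in chain-creation order), reference position `u`, `v`
#'   (first observation) and `n_seen`. The per-frame observations of every
#'   category are attached as attribute `"observations"` (data frame with
#'   columns `frame`, `category`, `u`, `v`).
#' @export
select_categories <- function(detections, lambda = 0.3, link_radius = 5) {
  stopifnot(is.list(detections), length(detections) >= 1,
            lambda > 0, lambda <= 1)
  K <- length(detections)
  chains_u <- numeric(0); chains_v <- numeric(0)  # last seen position
  ref_u <- numeric(0); ref_v <- numeric(0)
  count <- integer(0)
  obs <- vector("list", K)
  for (f in seq_len(K)) {
    det <- detections[[f]]
    nd <- nrow(det)
    assigned_chain <- integer(0); assigned_det <- integer(0)
    if (nd > 0 && length(chains_u) > 0) {
      # greedy: globally closest (chain, detection) pairs first
      d2 <- outer(chains_u, det$u, "-")^2 + outer(chains_v, det$v, "-")^2
      cand <- which(d2 <= link_radius^2, arr.ind = TRUE)
      if (nrow(cand) > 0) {
        cand <- cand[order(d2[cand]), , drop = FALSE]
        used_c <- logical(length(chains_u)); used_d <- logical(nd)
        for (r in seq_len(nrow(cand))) {
          ci <- cand[r, 1]; di <- cand[r, 2]
          if (!used_c[ci] && !used_d[di]) {
            used_c[ci] <- TRUE; used_d[di] <- TRUE
            assigned_chain <- c(assigned_chain, ci)
            assigned_det <- c(assigned_det, di)
          }
        }
      }
    }
    if (length(assigned_chain)) {
      chains_u[assigned_chain] <- det$u[assigned_det]
      chains_v[assigned_chain] <- det$v[assigned_det]
      count[assigned_chain] <- count[assigned_chain] + 1L
    }
    new_d <- setdiff(seq_len(nd), assigned_det)
    if (length(new_d)) {
      chains_u <- c(chains_u, det$u[new_d])
      chains_v <- c(chains_v, det$v[new_d])
      ref_u <- c(ref_u, det$u[new_d])
      ref_v <- c(ref_v, det$v[new_d])
      count <- c(count, rep(1L, length(new_d)))
    }
    seen <- c(assigned_chain,
              if (length(new_d)) seq.int(length(chains_u) - length(new_d) + 1L,
                                         length(chains_u)))
    pos_d <- c(assigned_det, new_d)
    obs[[f]] <- data.frame(frame = f, chain = seen,
                           u = det$u[pos_d], v = det$v[pos_d])
  }
  keep <- which(count >= lambda * K)
  if (length(keep) == 0)
    stop("empty category set: no feature chain persists in >= lambda*K frames")
  relabel <- integer(length(chains_u))
  relabel[keep] <- seq_along(keep)
  out <- data.frame(category = seq_along(keep),
                    u = ref_u[keep], v = ref_v[keep],
                    n_seen = count[keep])
  ob <- do.call(rbind, obs)
  ob <- ob[ob$chain %in% keep, ]
  ob$category <- relabel[ob$chain]
  ob <- ob[order(ob$frame, ob$category), c("frame", "category", "u", "v")]
  rownames(ob) <- NULL
  attr(out, "observations") <- ob
  out
}

#' Detect, classify and match one stereo frame pair
#'
#' Runs the full per-frame matching stage: FAST detection in both views,
#' patch classification, match-matrix construction and category
#' intersection.
#'
#' @param left,right grayscale frame matrices.
#' @param model a trained [train_classifier()] model.
#' @param threshold,nonmax_radius detector settings, see [detect_features()].
#' @return The [compute_matches()] data frame for the pair, with detection
#'   and classification counts attached as attribute `"counts"`.
#' @export
frame_matches <- function(left, right, model,
                          threshold = 0.08, nonmax_radius = 8) {
  n <- model$spec$n_categories
  side <- function(img) {
    det <- detect_features(img, threshold = threshold,
                           nonmax_radius = nonmax_radius)
    if (nrow(det) == 0)
      return(list(mm = build_match_matrix(
        data.frame(u = numeric(0), v = numeric(0),
                   category = integer(0), probability = numeric(0)), n),
        n_det = 0L))
    cls <- classify_patches(model, patch_stack(img, det))
    list(mm = build_match_matrix(
      data.frame(u = det$u, v = det$v,
                 category = cls$category, probability = cls$probability), n),
      n_det = nrow(det))
  }
  L <- side(left); R <- side(right)
  m <- compute_matches(L$mm, R$mm)
  attr(m, "counts") <- c(detected_left = L$n_det, detected_right = R$n_det,
                         matched = nrow(m))
  m
}
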