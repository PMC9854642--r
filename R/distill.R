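#' Tempered softmax
#'
#' Converts logits to probabilities at temperature `T`, with max-subtraction
#' so extreme logits cannot overflow. Higher temperatures smooth the
#' distribution, exposing the inter-class similarity structure ("dark
#' knowledge") that distillation transfers.
#'
#' @param z Numeric logit vector.
#' @param T Temperature, strictly positive (distillation default 4).
#' @return A probability vector summing to 1.
#' @export
softmax_t <- function(z, T = 1) {
  if (!is.numeric(T) || length(T) != 1L || T <= 0)
    stop_invalid("temperature T must be a positive scalar")
  z <- z / T
  e <- exp(z - max(z))
  e / sum(e)
}

P_FLOOR <- 1e-12  # probability floor inside every log()

#' Cross-entropy of a probability vector against a hard label
#'
#' @param p Probability vector.
#' @param label 0-based class index.
#' @return `-log p[label]`, with the probability floored at 1e-12.
#' @export
cross_entropy <- function(p, label) {
  if (length(label) != 1L || label < 0L || label >= length(p))
    stop_invalid("label ", label, " out of range for ", length(p), " classes")
  -log(max(p[label + 1L], P_FLOOR))
}

#' Multi-branch teacher loss
#'
#' The teacher is trained simultaneously on the raw image, the
#' attention-cropped object image, and N key-part images; its loss is the
#' sum of the per-branch cross-entropies:
#' `L_total = L_r + L_o + L_p`, with `L_p` the sum over part branches
#' (zero when no parts are used).
#'
#' @param p_raw,p_obj Probability vectors for the raw and object branches.
#' @param p_parts List of probability vectors for part branches (may be
#'   empty).
#' @param label 0-based class index.
#' @return A list of class `"teacher_loss_bundle"` with fields
#'   `l_r`, `l_o`, `l_p`, `l_total`.
#' @export
teacher_total_loss <- function(p_raw, p_obj, p_parts = list(), label) {
  C <- length(p_raw)
  if (length(p_obj) != C || any(vapply(p_parts, length, 1L) != C))
    stop_invalid("all probability vectors must have the same length")
  l_r <- cross_entropy(p_raw, label)
  l_o <- cross_entropy(p_obj, label)
  l_p <- if (length(p_parts)) sum(vapply(p_parts, cross_entropy, 0, label = label)) else 0
  structure(list(l_r = l_r, l_o = l_o, l_p = l_p, l_total = l_r + l_o + l_p),
            class = "teacher_loss_bundle")
}

kl_div <- function(p, q) {
  sum(p * (log(pmax(p, P_FLOOR)) - log(pmax(q, P_FLOOR))))
}

#' Classical logit-distillation loss
#'
#' KL divergence `KL(P_T || P_S)` between teacher and student class
#' distributions, both tempered by `T`.
#'
#' @param z_teacher,z_student Logit vectors over the same classes.
#' @param T Temperature.
#' @return A non-negative scalar, zero iff the tempered distributions
#'   coincide.
#' @export
kd_loss <- function(z_teacher, z_student, T = 4) {
  if (length(z_teacher) != length(z_student))
    stop_invalid("teacher and student logits must have the same length")
  kl_div(softmax_t(z_teacher, T), softmax_t(z_student, T))
}

#' Target / non-target binary split of a logit vector
#'
#' `p_t` is the tempered softmax probability of the target class and
#' `p_not_t` the summed probability of all other classes, so the pair is a
#' 2-class distribution.
#'
#' @param z Logit vector.
#' @param target 0-based target class index.
#' @param T Temperature (applied here as everywhere in the decoupled loss,
#'   so the decomposition identity holds at any temperature).
#' @return Named numeric `c(p_t, p_not_t)`.
#' @export
binary_split <- function(z, target, T = 4) {
  p <- softmax_t(z, T)
  pt <- p[target + 1L]
  c(p_t = pt, p_not_t = 1 - pt)
}

#' Non-target class distribution
#'
#' Softmax over the non-target logits only, i.e. the class distribution
#' renormalized after removing the target class. By construction it does
#' not depend on the target logit.
#'
#' @inheritParams binary_split
#' @return A probability vector of length `C - 1` (classes in original
#'   order, target omitted).
#' @export
nontarget_probs <- function(z, target, T = 4) {
  if (length(z) < 2L) stop_invalid("need at least 2 classes")
  softmax_t(z[-(target + 1L)], T)
}

#' Target-class knowledge distillation (TCKD)
#'
#' KL divergence between the teacher's and the student's binary
#' target/non-target splits.
#'
#' @param z_teacher,z_student Logit vectors.
#' @param target 0-based shared target index.
#' @param T Temperature.
#' @return Non-negative scalar.
#' @export
tckd <- function(z_teacher, z_student, target, T = 4) {
  kl_div(binary_split(z_teacher, target, T), binary_split(z_student, target, T))
}

#' Non-target-class knowledge distillation (NCKD)
#'
#' KL divergence between the teacher's and the student's renormalized
#' non-target distributions. With only two classes both distributions are
#' the degenerate `[1]`, so NCKD is 0.
#'
#' @inheritParams tckd
#' @return Non-negative scalar.
#' @export
nckd <- function(z_teacher, z_student, target, T = 4) {
  kl_div(nontarget_probs(z_teacher, target, T),
         nontarget_probs(z_student, target, T))
}

#' Decoupled knowledge distillation loss
#'
#' Classical distillation decomposes exactly as
#' `KD = TCKD + (1 - p_t^T) * NCKD`, where `p_t^T` is the teacher's tempered
#' target probability. When the teacher is confident (`p_t^T` near 1) the
#' non-target term -- which carries the inter-class similarity structure
#' that matters most in fine-grained recognition -- is suppressed. DKD
#' replaces the coupled weight with a free coefficient:
#' `DKD = TCKD + alpha * NCKD`.
#'
#' @inheritParams tckd
#' @param alpha Non-negative weight of the non-target term (default 2, the
#'   empirically best setting).
#' @return A list of class `"dkd_breakdown"` with fields `tckd`, `nckd`,
#'   `teacher_pt` (the teacher's tempered target probability), `alpha`, and
#'   `total = tckd + alpha * nckd`.
#' @examples
#' zt <- c(4, 1, 0); zs <- c(2, 2, 1)
#' dkd_loss(zt, zs, target = 0, T = 4, alpha = 2)
#' @export
dkd_loss <- function(z_teacher, z_student, target, T = 4, alpha = 2) {
  if (alpha < 0) stop_invalid("alpha must be >= 0")
  if (length(z_teacher) != length(z_student))
    stop_invalid("teacher and student logits must have the same length")
  tc <- tckd(z_teacher, z_student, target, T)
  nc <- nckd(z_teacher, z_student, target, T)
  pt <- unname(binary_split(z_teacher, target, T)["p_t"])
  structure(list(tckd = tc, nckd = nc, teacher_pt = pt, alpha = alpha,
                 total = tc + alpha * nc),
            class = "dkd_breakdown")
}

#' Student loss over augmentation streams
#'
#' During distillation the student sees several image streams per sample
#' (raw image, object/part crops from teacher attention, object/part crops
#' from student attention). The hard loss sums the cross-entropy of the
#' student's T=1 prediction on every stream against the label; the soft
#' loss sums the per-stream distillation loss against the teacher's logits
#' on the same stream; the total is their sum.
#'
#' @param streams A non-empty list; each element is a list with fields
#'   `z_student`, `z_teacher`, `label` (0-based).
#' @param T Temperature for the soft loss.
#' @param alpha Non-target weight (used when `soft_mode = "dkd"`).
#' @param soft_mode `"dkd"` (decoupled, default), `"kd"` (classical, i.e.
#'   the coupled `alpha = 1 - p_t^T` weighting), or `"none"`.
#' @return A list of class `"student_loss_bundle"` with `l_hard`, `l_soft`,
#'   `l_total`, plus mean diagnostic fields `tckd_mean`, `nckd_mean`,
#'   `teacher_pt_mean`.
#' @export
student_total_loss <- function(streams, T = 4, alpha = 2,
                               soft_mode = c("dkd", "kd", "none")) {
  soft_mode <- match.arg(soft_mode)
  if (!length(streams)) stop_invalid("streams must be non-empty")
  l_hard <- 0; l_soft <- 0
  tc <- nc <- pt <- numeric(0)
  for (s in streams) {
    l_hard <- l_hard + cross_entropy(softmax_t(s$z_student, 1), s$label)
    if (soft_mode != "none") {
      b <- dkd_loss(s$z_teacher, s$z_student, s$label, T = T, alpha = alpha)
      w <- if (soft_mode == "kd") 1 - b$teacher_pt else alpha
      l_soft <- l_soft + b$tckd + w * b$nckd
      tc <- c(tc, b$tckd); nc <- c(nc, b$nckd); pt <- c(pt, b$teacher_pt)
    }
  }
  structure(list(l_hard = l_hard, l_soft = l_soft, l_total = l_hard + l_soft,
                 tckd_mean = if (length(tc)) mean(tc) else 0,
                 nckd_mean = if (length(nc)) mean(nc) else 0,
                 teacher_pt_mean = if (length(pt)) mean(pt) else NA_real_),
            class = "student_loss_bundle")
}

# ---- analytic gradients (used by the training loops) -----------------------

# d CE(softmax(z, 1), label) / dz = p - onehot
ce_grad <- function(z, label) {
  g <- softmax_t(z, 1)
  g[label + 1L] <- g[label + 1L] - 1
  g
}

# Gradient of the decoupled loss w.r.t. the STUDENT logits. soft_mode "kd"
# uses the coupled weight (1 - teacher_pt), reproducing the classical KD
# gradient (s - t)/T exactly -- asserted against numerical differentiation
# in the tests.
dkd_grad_student <- function(z_teacher, z_student, target, T = 4, alpha = 2,
                             soft_mode = "dkd") {
  C <- length(z_student)
  s <- softmax_t(z_student, T)
  t <- softmax_t(z_teacher, T)
  ti <- target + 1L
  st <- s[ti]; tt <- t[ti]
  w <- if (soft_mode == "kd") 1 - tt else alpha
  # TCKD via the binary split
  gpt <- (1 - tt) / max(1 - st, P_FLOOR) - tt / max(st, P_FLOOR)
  g <- (-gpt * st / T) * s
  g[ti] <- g[ti] + gpt * st / T
  # NCKD is KL between softmaxes over the non-target logits; target entry 0
  if (C >= 3L && w != 0) {
    sh <- softmax_t(z_student[-ti], T)
    th <- softmax_t(z_teacher[-ti], T)
    g[-ti] <- g[-ti] + w * (sh - th) / T
  }
  g
}
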