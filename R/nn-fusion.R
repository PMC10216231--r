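#' Initialise the fusion classifier head
#'
#' A linear softmax classifier on the concatenation of the AE bottleneck
#' and the pooled CNN embedding (32 + 32 at full scale).
#'
#' @param d_in Fused embedding width.
#' @param n_classes Number of classes (2: truth, lie).
#' @return Dense parameter list.
#' @export
fusion_init <- function(d_in, n_classes = 2L) dense_init(d_in, n_classes)

#' Fuse the two embeddings and classify
#'
#' Concatenates the AE bottleneck and CNN embedding, applies dropout
#' (training only), a linear map and a softmax over \{truth, lie\}.
#'
#' @param ae_emb N x d1 matrix (or vector) of AE bottleneck features.
#' @param cnn_emb N x d2 matrix (or vector) of CNN pooled embeddings.
#' @param head_params From [fusion_init()] with `d_in = d1 + d2`.
#' @param p_drop Dropout probability on the fused vector.
#' @param train Logical.
#' @return List: `probs` (N x 2, rows on the simplex), `logits`, `fused`,
#'   `cache`.
#' @export
fuse_and_classify <- function(ae_emb, cnn_emb, head_params, p_drop = 0,
                              train = FALSE) {
  if (is.null(dim(ae_emb))) ae_emb <- matrix(ae_emb, nrow = 1L)
  if (is.null(dim(cnn_emb))) cnn_emb <- matrix(cnn_emb, nrow = 1L)
  if (nrow(ae_emb) != nrow(cnn_emb)) {
    abort("ae_emb and cnn_emb disagree on batch size")
  }
  fused <- cbind(ae_emb, cnn_emb)
  if (ncol(fused) != nrow(head_params$W)) {
    abort(sprintf("fused width %d, head expects %d",
                  ncol(fused), nrow(head_params$W)))
  }
  dr <- dropout_forward(fused, p_drop, train)
  de <- dense_forward(dr$out, head_params)
  probs <- row_softmax(de$out)
  list(probs = probs, logits = de$out, fused = fused,
       cache = list(drop = dr$cache, dense = de$cache,
                    d1 = ncol(ae_emb), probs = probs))
}

#' Backward pass through the fusion head
#'
#' @param d_logits N x 2 gradient w.r.t. the logits.
#' @param head_params,cache From [fuse_and_classify()].
#' @param d_fused_extra Optional N x d gradient applied directly to the
#'   fused embedding (the consistency path, which bypasses the head).
#' @return List: `d_ae`, `d_cnn`, `grads` (head gradients).
#' @keywords internal
fusion_backward <- function(d_logits, head_params, cache, d_fused_extra = NULL) {
  r <- dense_backward(d_logits, head_params, cache$dense)
  d_fused <- dropout_backward(r$dx, cache$drop)
  if (!is.null(d_fused_extra)) d_fused <- d_fused + d_fused_extra
  d1 <- cache$d1
  list(d_ae = d_fused[, seq_len(d1), drop = FALSE],
       d_cnn = d_fused[, -seq_len(d1), drop = FALSE],
       grads = r$grads)
}

#' Exponential-moving-average teacher update
#'
#' Updates every teacher tensor elementwise as
#' `teacher <- alpha * teacher + (1 - alpha) * student`, recursing through
#' congruent nested parameter lists. The student is untouched and no
#' gradient flows through the teacher.
#'
#' @param teacher_params,student_params Congruent nested lists of numeric
#'   arrays.
#' @param alpha_ema Smoothing coefficient in `[0, 1]`; 1 freezes the
#'   teacher, 0 copies the student.
#' @return Updated teacher parameter structure.
#' @export
ema_update <- function(teacher_params, student_params, alpha_ema = 0.99) {
  stopifnot(alpha_ema >= 0, alpha_ema <= 1)
  if (is.list(teacher_params)) {
    if (!is.list(student_params) ||
        !identical(names(teacher_params), names(student_params))) {
      abort("teacher and student parameter structures are not congruent")
    }
    return(purrr::map2(teacher_params, student_params, ema_update,
                       alpha_ema = alpha_ema))
  }
  if (!identical(dim(teacher_params), dim(student_params)) ||
      length(teacher_params) != length(student_params)) {
    abort("teacher and student parameter structures are not congruent")
  }
  alpha_ema * teacher_params + (1 - alpha_ema) * student_params
}
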