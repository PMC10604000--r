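# Shared test helpers: landmark-set transforms and independent re-computation
# of the parameter definitions (the oracle deliberately uses its own trig
# rather than the package's angle machinery).

ALL_LEVELS <- c(paste0("C", 2:7), paste0("T", 1:12), paste0("L", 1:5))
CORNER_ROLES <- c("superior_anterior", "superior_posterior",
                  "inferior_anterior", "inferior_posterior")

# apply a point transform (function c(x,y) -> c(x,y)) to every landmark
transform_landmarks <- function(lm, fn, facing = lm$facing, spacing = lm$spacing) {
  out <- lm
  out$vertebrae <- lapply(lm$vertebrae, function(v) {
    nv <- lapply(v[CORNER_ROLES], fn)
    nv$centroid <- Reduce(`+`, nv) / 4
    structure(nv, class = "vertebra_landmarks")
  })
  out$sacral_endplate <- list(anterior = fn(lm$sacral_endplate$anterior),
                              posterior = fn(lm$sacral_endplate$posterior),
                              midpoint = fn(lm$sacral_endplate$midpoint))
  out$femoral_head_center <- fn(lm$femoral_head_center)
  out$facing <- facing
  out$spacing <- spacing
  out
}

signed_values <- function(result) stats::setNames(result$value, result$parameter)

# Independent oracle: the 13 definitions recomputed from raw corner
# coordinates with plain trigonometry.
oracle_params <- function(lm) {
  fac <- if (lm$facing == "+x") 1 else -1
  slope <- function(a, p) {
    atan2(p[2] - a[2], fac * (a[1] - p[1])) * 180 / pi
  }
  ep <- lm$sacral_endplate
  ss <- slope(ep$anterior, ep$posterior)
  u <- ep$midpoint - lm$femoral_head_center
  pt <- atan2(fac * u[1], -u[2]) * 180 / pi
  s_c2i <- slope(lm$vertebrae$C2$inferior_anterior, lm$vertebrae$C2$inferior_posterior)
  s_c7i <- slope(lm$vertebrae$C7$inferior_anterior, lm$vertebrae$C7$inferior_posterior)
  s_t1s <- slope(lm$vertebrae$T1$superior_anterior, lm$vertebrae$T1$superior_posterior)
  s_l1s <- slope(lm$vertebrae$L1$superior_anterior, lm$vertebrae$L1$superior_posterior)
  sva <- function(from, to) fac * (from[1] - to[1]) * lm$spacing
  c(c2i = pt + s_c2i, c2s = s_c2i, c27l = s_c2i - s_c7i,
    t1i = pt + s_t1s, t1s = s_t1s, tk = s_l1s - s_t1s,
    l1i = pt + s_l1s, ll = ss - s_l1s, ss = ss, pt = pt, pi = pt + ss,
    c2_7_sva = sva(lm$vertebrae$C2$centroid, lm$vertebrae$C7$superior_posterior),
    c7_sva = sva(lm$vertebrae$C7$centroid, ep$posterior))
}

# ICC(2,1) oracle: mean squares taken from a two-way stats::aov fit on the
# long-format data, then the standard absolute-agreement formula.
icc21_aov_oracle <- function(x) {
  n <- nrow(x); k <- ncol(x)
  long <- data.frame(v = as.vector(x),
                     case = factor(rep(seq_len(n), k)),
                     rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(v ~ case + rater, data = long))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# a small complete scene measured through the raster path
measured_scene <- function(seed = 1, targets = list()) {
  spec <- spec_from_targets(targets, seed = seed)
  masks <- rasterize_spec(spec)
  lm <- label_structures(masks, facing = spec$facing, spacing = spec$spacing)
  list(spec = spec, masks = masks, landmarks = lm,
       truth = ground_truth(spec), result = compute_all(lm))
}
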