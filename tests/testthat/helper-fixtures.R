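# Shared in-code fixtures: feature/peak-group builders with sensible
# defaults, paired target+decoy builders for the training filter, and naive
# brute-force oracles used in the equivalence tests.

make_feature <- function(id = "F1", run = "run1", mz = 300, rt = 5,
                         ccs = 150, sn = 30, height = 1000,
                         frag_int = c(900, 500, 120),
                         frag_mz = NULL) {
  if (is.null(frag_mz))
    frag_mz <- seq(100, by = 17.3, length.out = length(frag_int))
  deconvoluted_feature(id, run, mz, rt, ccs, sn, height,
                       data.frame(mz = frag_mz, intensity = frag_int))
}

make_precursor <- function(mz = 300, area = 5e4, height = 1000,
                           fwhm = 0.1, rt = 5, mass_error_ppm = 1,
                           sn = 30) {
  list(mz = mz, area = area, height = height, fwhm = fwhm, rt = rt,
       mass_error_ppm = mass_error_ppm, sn = sn)
}

# fragments co-eluting perfectly with the default precursor
make_fragments <- function(n = 4, height = NULL, area = NULL, rt = 5,
                           fwhm = 0.1, mass_error_ppm = 1,
                           expected = NULL) {
  if (n == 0)
    return(data.frame(mz = numeric(), expected_intensity = numeric(),
                      area = numeric(), height = numeric(),
                      fwhm = numeric(), rt = numeric(),
                      mass_error_ppm = numeric()))
  if (is.null(height)) height <- 1000 * 0.6^seq_len(n)
  if (is.null(area)) area <- height * fwhm * 25
  if (is.null(expected)) expected <- height
  data.frame(mz = seq(90, by = 13.7, length.out = n),
             expected_intensity = expected, area = area, height = height,
             fwhm = fwhm, rt = rt, mass_error_ppm = mass_error_ppm)
}

make_group <- function(id = "G1", run = "run1", label = "target",
                       precursor = make_precursor(),
                       fragments = make_fragments(),
                       expected_rt = 5, expected_ccs = 150,
                       observed_ccs = 150, partner = NA_character_) {
  peak_group(id, run, label, precursor, fragments, expected_rt,
             expected_ccs, observed_ccs, partner)
}

# a target and its mirrored decoy (same fragment count and intensity
# profile, different fragment m/z), as the extraction step would report
make_pair_groups <- function(id = "G1", run = "run1",
                             precursor = make_precursor(),
                             fragments = make_fragments(),
                             decoy_fragments = NULL) {
  if (is.null(decoy_fragments)) {
    decoy_fragments <- fragments
    decoy_fragments$mz <- fragments$mz + 31.1
  }
  list(target = make_group(id, run, "target", precursor, fragments),
       decoy = make_group(paste0("DECOY_", id), run, "decoy", precursor,
                          decoy_fragments, partner = id))
}

# independent recomputation of the seven descriptors, written as directly
# from their definitions as possible
brute_force_descriptors <- function(group) {
  f <- group$fragments
  p <- group$precursor
  out <- c(cos_sim = NA_real_, rtdiff_sd = NA_real_,
           rtdiff_mean = NA_real_, fwhmdiff_sd = NA_real_,
           fwhmdiff_mean = NA_real_, masserror_sd = NA_real_,
           masserror_mean = NA_real_)
  if (nrow(f) < 2) return(out)
  a <- f$area; e <- f$expected_intensity
  ok <- !is.na(a) & !is.na(e)
  rts <- f$rt[!is.na(f$rt)]
  fws <- f$fwhm[!is.na(f$fwhm)]
  mes <- f$mass_error_ppm[!is.na(f$mass_error_ppm)]
  if (sum(ok) < 2 || length(rts) < 2 || length(fws) < 2 ||
      length(mes) < 2 || is.na(p$rt) || is.na(p$fwhm))
    return(out)
  dot <- 0; na2 <- 0; nb2 <- 0
  for (i in which(ok)) {
    dot <- dot + a[i] * e[i]; na2 <- na2 + a[i]^2; nb2 <- nb2 + e[i]^2
  }
  samp_sd <- function(x) {
    m <- sum(x) / length(x)
    sqrt(sum((x - m)^2) / (length(x) - 1))
  }
  out["cos_sim"] <- dot / (sqrt(na2) * sqrt(nb2))
  out["rtdiff_mean"] <- mean(p$rt - rts)
  out["rtdiff_sd"] <- samp_sd(p$rt - rts)
  out["fwhmdiff_mean"] <- mean(p$fwhm - fws)
  out["fwhmdiff_sd"] <- samp_sd(p$fwhm - fws)
  out["masserror_mean"] <- mean(mes)
  out["masserror_sd"] <- samp_sd(mes)
  out
}

# enumeration oracle for match_features
brute_force_match <- function(features, library, mass_tol = 0.01,
                              rt_tol = 0.2, ccs_tol_pct = 0.8) {
  res <- list()
  for (e in library) {
    m <- r <- cc <- mrc <- 0L
    for (f in features) {
      hit_m <- abs(f$precursor_mz - e$precursor_mz) <= mass_tol
      hit_r <- !is.na(f$rt) && !is.na(e$rt) && abs(f$rt - e$rt) <= rt_tol
      hit_c <- !is.na(f$ccs) && !is.na(e$ccs) &&
        100 * abs(f$ccs - e$ccs) / e$ccs <= ccs_tol_pct
      if (hit_m) m <- m + 1L
      if (hit_m && hit_r) r <- r + 1L
      if (hit_m && hit_c) cc <- cc + 1L
      if (hit_m && hit_r && hit_c) mrc <- mrc + 1L
    }
    res[[length(res) + 1L]] <- data.frame(name = e$name, mass_only = m,
                                          mass_rt = r, mass_ccs = cc,
                                          mass_rt_ccs = mrc)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# random peak-group for property tests (may contain missing metrics)
random_group <- function(i, with_missing = TRUE) {
  n <- sample(2:12, 1)
  f <- data.frame(mz = sort(runif(n, 60, 400)),
                  expected_intensity = rlnorm(n, 8, 1),
                  area = rlnorm(n, 9, 1), height = rlnorm(n, 7, 1),
                  fwhm = runif(n, 0.05, 0.2), rt = runif(n, 4.8, 5.2),
                  mass_error_ppm = rnorm(n, 0, 6))
  if (with_missing && runif(1) < 0.3)
    f$area[sample(n, 1)] <- NA
  make_group(paste0("R", i), "run1", "target",
             make_precursor(rt = 5.01, fwhm = runif(1, 0.05, 0.2)), f)
}

path_to_library <- function() {
  system.file("extdata", "synthetic_library_64.msp",
              package = "peakdecoder")
}
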