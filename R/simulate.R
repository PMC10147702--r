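# Synthetic LC-IM-MS DIA data generator.
#
# The generator models the XIC summary metrics directly -- the only surface
# the algorithm ever consumes -- not raw spectra.  True peak-groups have
# fragments that co-elute tightly with their precursor (small RT jitter,
# small mass error, FWHM tracking the precursor, areas proportional to the
# expected intensity profile); false peak-groups keep realistic precursor
# properties (mirroring the paired-decoy construction) but have broken
# co-elution: large RT jitter, large mass errors, independent FWHM and an
# intensity profile decorrelated from the expected vector.  A configurable
# fraction of true-group fragments is corrupted (area zeroed or RT shifted)
# to exercise the interference rules of the training filter.

#' Simulation configuration
#'
#' @param n_true_groups number of true (target-like) peak-groups
#' @param n_false_groups number of false (decoy-like) peak-groups, paired
#'   one-to-one with the first `n_false_groups` true groups (must not
#'   exceed `n_true_groups`)
#' @param n_runs number of runs (replicates)
#' @param rt_jitter_sd_true,rt_jitter_sd_false fragment RT jitter around
#'   the precursor apex (minutes)
#' @param fwhm_mean,fwhm_sd LC peak width at half maximum (minutes)
#' @param mass_error_sd_true,mass_error_sd_false fragment ppm mass error
#' @param intensity_decay geometric decay of the fragment intensity profile
#' @param interference_rate fraction of true-group fragments corrupted
#'   (area zeroed or RT shifted beyond the 0.1 min co-elution rule)
#' @param sn_meanlog,sn_sdlog lognormal parameters of the precursor S/N
#' @param fragment_count_range inclusive range of fragments per group
#' @param mz_range,rt_range precursor m/z (Th) and RT (minutes) ranges
#' @param seed integer seed; generation is fully reproducible
#' @return object of class `simulation_config`
#' @export
simulation_config <- function(n_true_groups = 500, n_false_groups = 500,
                              n_runs = 3,
                              rt_jitter_sd_true = 0.01,
                              rt_jitter_sd_false = 0.15,
                              fwhm_mean = 0.08, fwhm_sd = 0.015,
                              mass_error_sd_true = 3,
                              mass_error_sd_false = 12,
                              intensity_decay = 0.65,
                              interference_rate = 0.05,
                              sn_meanlog = log(60), sn_sdlog = 0.5,
                              fragment_count_range = c(3, 16),
                              mz_range = c(80, 800),
                              rt_range = c(0.5, 8.5), seed = 1L) {
  cfg <- list(n_true_groups = n_true_groups,
              n_false_groups = n_false_groups, n_runs = n_runs,
              rt_jitter_sd_true = rt_jitter_sd_true,
              rt_jitter_sd_false = rt_jitter_sd_false,
              fwhm_mean = fwhm_mean, fwhm_sd = fwhm_sd,
              mass_error_sd_true = mass_error_sd_true,
              mass_error_sd_false = mass_error_sd_false,
              intensity_decay = intensity_decay,
              interference_rate = interference_rate,
              sn_meanlog = sn_meanlog, sn_sdlog = sn_sdlog,
              fragment_count_range = fragment_count_range,
              mz_range = mz_range, rt_range = rt_range,
              seed = as.integer(seed))
  sds <- c(cfg$rt_jitter_sd_true, cfg$rt_jitter_sd_false, cfg$fwhm_sd,
           cfg$mass_error_sd_true, cfg$mass_error_sd_false)
  if (any(sds < 0)) stop("standard deviations must be >= 0")
  if (cfg$interference_rate < 0 || cfg$interference_rate > 1)
    stop("interference_rate must be in [0, 1]")
  if (cfg$n_false_groups > cfg$n_true_groups)
    stop("n_false_groups must not exceed n_true_groups (paired design)")
  if (cfg$fragment_count_range[1] < 2 || cfg$fragment_count_range[2] > 16)
    stop("fragment_count_range must lie within [2, 16]")
  structure(cfg, class = "simulation_config")
}

#' Read a simulation configuration from a key = value text file
#'
#' Plain-text, TOML-style scalar assignments (`#` comments allowed); keys
#' are [simulation_config()] argument names, two-element ranges are written
#' comma-separated (e.g. `fragment_count_range = 3, 16`).  Unknown keys are
#' an error; unspecified keys keep their defaults.
#'
#' @param path config file path
#' @return object of class `simulation_config`
#' @export
read_simulation_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- lines[grepl("=", lines, fixed = TRUE)]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- parse_numeric(strsplit(trimws(paste(kv[-1], collapse = "=")),
                                  ",")[[1]])
    if (!key %in% names(formals(simulation_config)))
      stop("unknown simulation config key: ", key)
    args[[key]] <- val
  }
  do.call(simulation_config, args)
}

# rough drift-tube CCS trend for singly charged small molecules
.sim_ccs <- function(mz) 120 * (mz / 300)^0.5

# fixed-point-free permutation: false-group intensity profiles must be
# decorrelated from the expected vector, which an identity (or partial
# identity) assignment at small fragment counts would defeat
.derange <- function(k) {
  if (k < 2) return(seq_len(k))
  repeat {
    p <- sample.int(k)
    if (!any(p == seq_len(k))) return(p)
  }
}

# base (run-independent) properties of the true peak-groups
.sim_bases <- function(cfg) {
  n <- cfg$n_true_groups
  mz <- stats::runif(n, cfg$mz_range[1], cfg$mz_range[2])
  k_rng <- cfg$fragment_count_range
  lapply(seq_len(n), function(i) {
    k <- sample(seq(k_rng[1], k_rng[2]), 1L)
    height <- stats::rlnorm(1, log(5e4), 1)
    profile <- cfg$intensity_decay^(seq_len(k) - 1) *
      stats::rlnorm(k, 0, 0.25)
    profile <- sort(profile, decreasing = TRUE)
    list(id = sprintf("PG%04d", i), mz = mz[i],
         rt = stats::runif(1, cfg$rt_range[1], cfg$rt_range[2]),
         ccs = .sim_ccs(mz[i]) * stats::rlnorm(1, 0, 0.03),
         sn = stats::rlnorm(1, cfg$sn_meanlog, cfg$sn_sdlog),
         height = height, k = k,
         frag_mz = sort(stats::runif(k, 50, max(51, mz[i] - 1))),
         frag_int = pmin(height * profile, 1.25 * height),
         # fragment m/z of the paired false group (same profile, other ions)
         decoy_mz = sort(stats::runif(k, 50, max(51, mz[i] - 1))))
  })
}

# one run's XIC rows for a true or false group
.sim_group_run <- function(base, run, run_shift, cfg, false_group) {
  rt_sd <- if (false_group) cfg$rt_jitter_sd_false else cfg$rt_jitter_sd_true
  me_sd <- if (false_group) cfg$mass_error_sd_false else cfg$mass_error_sd_true
  k <- base$k
  prt <- base$rt + run_shift + stats::rnorm(1, 0, 0.005)
  pfw <- max(0.02, stats::rnorm(1, cfg$fwhm_mean, cfg$fwhm_sd))
  ph <- base$height * stats::rlnorm(1, 0, 0.2)
  pa <- ph * pfw * 25 * stats::rlnorm(1, 0, 0.05)
  if (false_group) {
    fh <- base$frag_int[.derange(k)] * stats::rlnorm(k, 0, 0.5)
    fr <- prt + stats::rnorm(k, 0, rt_sd)
    ff <- pmax(0.02, stats::rnorm(k, cfg$fwhm_mean, cfg$fwhm_sd))
  } else {
    fh <- base$frag_int * stats::rlnorm(k, 0, 0.15)
    fr <- prt + stats::rnorm(k, 0, rt_sd)
    ff <- pmax(0.02, pfw + stats::rnorm(k, 0, 0.008))
  }
  fa <- fh * ff * 25 * stats::rlnorm(k, 0, 0.08)
  fe <- stats::rnorm(k, 0, me_sd)
  if (!false_group && cfg$interference_rate > 0) {
    hit <- which(stats::runif(k) < cfg$interference_rate)
    for (j in hit) {
      if (stats::runif(1) < 0.5) fa[j] <- 0
      else fr[j] <- fr[j] + 0.12 + stats::rexp(1, 10)
    }
  }
  peak_group(
    group_id = if (false_group) paste0("DECOY_", base$id) else base$id,
    run_id = run,
    label = if (false_group) "decoy" else "target",
    precursor = list(mz = base$mz, area = pa, height = ph, fwhm = pfw,
                     rt = prt,
                     mass_error_ppm = stats::rnorm(1, 0,
                                                   cfg$mass_error_sd_true),
                     sn = base$sn * stats::rlnorm(1, 0, 0.1)),
    fragments = data.frame(
      mz = if (false_group) base$decoy_mz else base$frag_mz,
      expected_intensity = base$frag_int,
      area = fa, height = fh, fwhm = ff, rt = fr, mass_error_ppm = fe),
    expected_rt = base$rt, expected_ccs = base$ccs,
    observed_ccs = base$ccs * (1 + stats::rnorm(1, 0, 0.1) / 100),
    partner_id = if (false_group) base$id else NA_character_)
}

#' Simulate an alignment table, XIC report and truth labels
#'
#' Writes three files into `dir`: `alignment.tsv` (the true peak-groups as
#' deconvoluted features, canonical simple_tsv dialect), `training_xic.csv`
#' (per-run XIC metrics for the true groups labelled `target` and their
#' paired false groups labelled `decoy`), and `truth.tsv` (group id to
#' true/false).  All outputs are readable by the package's readers and
#' byte-identical across repeated calls with the same config.
#'
#' @param cfg a [simulation_config()]
#' @param dir output directory (created if needed)
#' @return list with paths `alignment`, `xic_report`, `truth`, the
#'   `groups` (list of [peak_group()]) and the `truth` data frame
#' @export
simulate_peakgroups <- function(cfg, dir = tempfile("pdsim")) {
  stopifnot(inherits(cfg, "simulation_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  bases <- .sim_bases(cfg)
  runs <- sprintf("run%02d", seq_len(cfg$n_runs))
  run_shift <- stats::rnorm(cfg$n_runs, 0, 0.02)

  groups <- list()
  for (r in seq_along(runs)) {
    for (i in seq_along(bases)) {
      groups[[length(groups) + 1L]] <-
        .sim_group_run(bases[[i]], runs[r], run_shift[r], cfg, FALSE)
      if (i <= cfg$n_false_groups)
        groups[[length(groups) + 1L]] <-
          .sim_group_run(bases[[i]], runs[r], run_shift[r], cfg, TRUE)
    }
  }

  aln <- data.frame(
    FeatureId = vapply(bases, `[[`, "", "id"),
    RunId = runs[1],
    PrecursorMz = .fmt(vapply(bases, `[[`, 0, "mz"), 5),
    RT = .fmt(vapply(bases, `[[`, 0, "rt"), 4),
    CCS = .fmt(vapply(bases, `[[`, 0, "ccs"), 2),
    SN = .fmt(vapply(bases, `[[`, 0, "sn"), 2),
    Height = .fmt(vapply(bases, `[[`, 0, "height"), 1),
    MS2 = vapply(bases, function(b)
      paste(sprintf("%s:%s", .fmt(b$frag_mz, 5), .fmt(b$frag_int, 1)),
            collapse = " "), ""))
  aln_path <- file.path(dir, "alignment.tsv")
  utils::write.table(aln, aln_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  xic_path <- file.path(dir, "training_xic.csv")
  write_xic_report(groups, xic_path)

  truth <- data.frame(
    group_id = c(vapply(bases, `[[`, "", "id"),
                 paste0("DECOY_",
                        vapply(bases[seq_len(cfg$n_false_groups)], `[[`,
                               "", "id"))),
    truth = rep(c("true", "false"),
                c(cfg$n_true_groups, cfg$n_false_groups)))
  truth_path <- file.path(dir, "truth.tsv")
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  list(alignment = aln_path, xic_report = xic_path, truth = truth_path,
       groups = groups, truth_labels = truth)
}

.fmt <- function(x, digits) {
  ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "f"))
}

#' Simulate a query XIC report from a library
#'
#' Emulates a spiked-standard experiment: metabolites in `present` are
#' emitted as true peak-groups at their library coordinates (RT, CCS,
#' fragment profile), while absent metabolites are emitted as noise groups
#' (random RT, perturbed CCS, decorrelated fragment intensities) or omitted.
#' Enables recall and FDR measurement of the full pipeline.
#'
#' @param library list of [library_entry()] objects
#' @param present character vector of library names truly present
#' @param cfg a [simulation_config()] (uses its jitter/error fields, run
#'   count and seed)
#' @param dir output directory
#' @param absent_mode emit absent metabolites as `"noise"` groups or
#'   `"omit"` them
#' @return list with path `xic_report`, the `groups`, and `truth` data
#'   frame (metabolite, truth)
#' @export
simulate_query <- function(library, present, cfg, dir = tempfile("pdquery"),
                           absent_mode = c("noise", "omit")) {
  absent_mode <- match.arg(absent_mode)
  nm <- vapply(library, `[[`, "", "name")
  stopifnot(all(present %in% nm))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed + 1000003L)
  runs <- sprintf("run%02d", seq_len(cfg$n_runs))
  run_shift <- stats::rnorm(cfg$n_runs, 0, 0.02)
  groups <- list()
  for (e in library) {
    is_present <- e$name %in% present
    if (!is_present && absent_mode == "omit") next
    k <- nrow(e$fragments)
    base_rt <- if (is_present) e$rt + stats::rnorm(1, 0, 0.03)
    else stats::runif(1, cfg$rt_range[1], cfg$rt_range[2])
    # absent metabolites are interference picked up at the library
    # coordinates: random apex RT, the CCS of an unrelated molecule and a
    # mass error spread across the extraction window
    base_ccs <- if (is_present) e$ccs * (1 + stats::rnorm(1, 0, 0.15) / 100)
    else e$ccs * (1 + stats::rnorm(1, 0, 3) / 100)
    pme <- if (is_present) stats::rnorm(1, 0, 3)
    else stats::runif(1, -25, 25)
    height <- stats::rlnorm(1, log(3e4), 0.5)
    rt_sd <- if (is_present) cfg$rt_jitter_sd_true else cfg$rt_jitter_sd_false
    me_sd <- if (is_present) cfg$mass_error_sd_true
    else cfg$mass_error_sd_false
    for (r in seq_along(runs)) {
      prt <- base_rt + run_shift[r] + stats::rnorm(1, 0, 0.005)
      pfw <- max(0.02, stats::rnorm(1, cfg$fwhm_mean, cfg$fwhm_sd))
      ph <- height * stats::rlnorm(1, 0, 0.2)
      frg <- data.frame(mz = numeric(), expected_intensity = numeric(),
                        area = numeric(), height = numeric(),
                        fwhm = numeric(), rt = numeric(),
                        mass_error_ppm = numeric())
      if (k > 0) {
        scale <- ph / max(e$fragments$intensity)
        fh <- if (is_present)
          e$fragments$intensity * scale * stats::rlnorm(k, 0, 0.15)
        else e$fragments$intensity[.derange(k)] * scale *
          stats::rlnorm(k, 0, 0.6)
        ff <- if (is_present) pmax(0.02, pfw + stats::rnorm(k, 0, 0.008))
        else pmax(0.02, stats::rnorm(k, cfg$fwhm_mean, cfg$fwhm_sd))
        frg <- data.frame(
          mz = e$fragments$mz, expected_intensity = e$fragments$intensity,
          area = fh * ff * 25 * stats::rlnorm(k, 0, 0.08), height = fh,
          fwhm = ff, rt = prt + stats::rnorm(k, 0, rt_sd),
          mass_error_ppm = stats::rnorm(k, 0, me_sd))
      }
      groups[[length(groups) + 1L]] <- peak_group(
        group_id = e$name, run_id = runs[r], label = "query",
        precursor = list(mz = e$precursor_mz * (1 + pme * 1e-6),
                         area = ph * pfw * 25, height = ph, fwhm = pfw,
                         rt = prt, mass_error_ppm = pme,
                         sn = stats::rlnorm(1, log(100), 0.3)),
        fragments = frg, expected_rt = e$rt, expected_ccs = e$ccs,
        observed_ccs = base_ccs * (1 + stats::rnorm(1, 0, 0.05) / 100))
    }
  }
  xic_path <- file.path(dir, "query_xic.csv")
  write_xic_report(groups, xic_path)
  truth <- data.frame(metabolite = nm,
                      truth = ifelse(nm %in% present, "true", "false"))
  list(xic_report = xic_path, groups = groups, truth = truth)
}
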