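#' Platform noise model for synthetic segmentations
#'
#' Describes how one measurement platform distorts the true allele-specific
#' segmentation of a tumour genome: breakpoint placement jitter, the chance
#' of missing an injected event outright, a genome-wide rate of spurious
#' breakpoints (short runs of perturbed allele state, the mechanism by which
#' low sequencing coverage inflates scar scores), and probe-level Log2/BAF
#' noise for rendered tracks.
#'
#' @param label Platform label.
#' @param breakpoint_jitter_sd SD (bp) of the Gaussian shift applied to each
#'   true breakpoint.
#' @param p_miss_event Probability that an individual injected event is
#'   absent from the platform's view.
#' @param p_spurious_breakpoint Expected number of spurious breakpoints per
#'   100 Mb.
#' @param frac_spurious_telomeric Fraction of spurious breakpoints anchored
#'   at a chromosome end (their perturbed run extends inward from the
#'   telomere), reflecting the concentration of coverage artefacts in
#'   poorly mappable subtelomeric sequence; these create artefactual
#'   telomeric allelic imbalance.
#' @param probe_spacing Distance (bp) between rendered probes.
#' @param log2_noise_sd,baf_noise_sd Probe-level noise SDs.
#' @return A list of class `platform_model`.
#' @export
platform_model <- function(label, breakpoint_jitter_sd = 0, p_miss_event = 0,
                           p_spurious_breakpoint = 0, probe_spacing = 1600,
                           log2_noise_sd = 0, baf_noise_sd = 0,
                           frac_spurious_telomeric = 0.1) {
  stopifnot(p_miss_event >= 0, p_miss_event <= 1,
            breakpoint_jitter_sd >= 0, p_spurious_breakpoint >= 0,
            probe_spacing > 0, log2_noise_sd >= 0, baf_noise_sd >= 0,
            frac_spurious_telomeric >= 0, frac_spurious_telomeric <= 1)
  structure(list(label = label, breakpoint_jitter_sd = breakpoint_jitter_sd,
                 p_miss_event = p_miss_event,
                 p_spurious_breakpoint = p_spurious_breakpoint,
                 probe_spacing = probe_spacing, log2_noise_sd = log2_noise_sd,
                 baf_noise_sd = baf_noise_sd,
                 frac_spurious_telomeric = frac_spurious_telomeric),
            class = "platform_model")
}

#' Shipped platform presets
#'
#' Noise tiers emulating a SNP array, deep (~70x) WGS and downsampled WGS at
#' ~30x, ~15x and ~10x nominal coverage. Across the WGS tiers, lower coverage
#' never decreases the spurious-breakpoint rate or the Log2 noise — the
#' mechanism by which downsampling inflates scar scores — while the
#' per-event miss probability stays flat: reduced coverage mainly adds noise
#' rather than hiding multi-megabase events.
#'
#' @return Named list of [platform_model()] objects: `array`, `wgs70x`,
#'   `wgs30x`, `wgs15x`, `wgs10x`.
#' @export
platform_presets <- function() {
  list(
    array  = platform_model("array",  breakpoint_jitter_sd = 5e4, p_miss_event = 0.03,
                            p_spurious_breakpoint = 0.02, probe_spacing = 1700,
                            log2_noise_sd = 0.16, baf_noise_sd = 0.04),
    wgs70x = platform_model("wgs70x", breakpoint_jitter_sd = 1e4, p_miss_event = 0.01,
                            p_spurious_breakpoint = 0.02, probe_spacing = 1600,
                            log2_noise_sd = 0.08, baf_noise_sd = 0.02),
    wgs30x = platform_model("wgs30x", breakpoint_jitter_sd = 2.5e4, p_miss_event = 0.01,
                            p_spurious_breakpoint = 0.3, probe_spacing = 1600,
                            log2_noise_sd = 0.12, baf_noise_sd = 0.04),
    wgs15x = platform_model("wgs15x", breakpoint_jitter_sd = 6e4, p_miss_event = 0.01,
                            p_spurious_breakpoint = 1.0, probe_spacing = 1600,
                            log2_noise_sd = 0.18, baf_noise_sd = 0.07),
    wgs10x = platform_model("wgs10x", breakpoint_jitter_sd = 1e5, p_miss_event = 0.01,
                            p_spurious_breakpoint = 2.0, probe_spacing = 1600,
                            log2_noise_sd = 0.25, baf_noise_sd = 0.10)
  )
}

archetype_means <- function(archetype) {
  # Poisson means per event class; chosen so HR-deficient truths score ~85
  # (>= 60 in expectation) and proficient ones ~8 (<= 20): each LOH or
  # interstitial-switch event also generates two LSTs, and terminal AI events
  # of >= 10 Mb add one more.
  switch(archetype,
         hr_deficient = c(tai = 15, loh = 12, lst = 12),
         hr_proficient = c(tai = 1.5, loh = 1, lst = 1),
         stop("unknown archetype '", archetype, "'", call. = FALSE))
}

#' Simulate a ground-truth tumour segmentation
#'
#' Builds an allele-specific copy-number profile on an all-`1+1` diploid
#' background by injecting three classes of scar events with known counts:
#' interstitial LOH regions (`1+0`, length Uniform(16, 40) Mb), terminal
#' allelic-imbalance events (`2+1` or `3+1`, length Uniform(5, 30) Mb,
#' confined to one arm), and interstitial state switches (`2+2`, length
#' Uniform(12, 25) Mb) whose two boundaries are large-scale transitions.
#' Event counts are Poisson draws with archetype-specific means
#' (HR-deficient profiles score well above the 42 threshold, proficient ones
#' well below). Events are placed by rejection sampling with 13 Mb clearance
#' from each other, from arm boundaries and from the centromere; an event
#' that cannot be placed after 100 attempts is skipped and the recorded
#' truth count decremented.
#'
#' @param build A `genome_build`.
#' @param archetype `"hr_deficient"` or `"hr_proficient"`.
#' @param seed Integer seed; the simulation is deterministic given it.
#' @param sample_id Sample label.
#' @return List with `profile` (segment tibble), `events` (tibble of
#'   injected events) and `truth` (list: `seed`, `archetype`, counts
#'   `n_tai`, `n_loh`, `n_lst_breaks`).
#' @export
simulate_true_profile <- function(build, archetype = c("hr_deficient", "hr_proficient"),
                                  seed = 1, sample_id = "synthetic") {
  archetype <- match.arg(archetype)
  mu <- archetype_means(archetype)
  rng <- local_rng(seed)
  counts <- c(tai = stats::rpois(1, mu["tai"]),
              loh = stats::rpois(1, mu["loh"]),
              lst = stats::rpois(1, mu["lst"]))
  arms <- arm_table(build)
  # clearance between events and from arm ends: comfortably above the 10 Mb
  # flank rule so platform jitter cannot push a qualifying flank below it
  margin <- 13e6
  placed <- list()
  events <- list()
  skip <- c(tai = 0L, loh = 0L, lst = 0L)

  place_interstitial <- function(len) {
    for (attempt in seq_len(100)) {
      arm <- arms[sample.int(nrow(arms), 1, prob = arms$len), , drop = FALSE]
      lo <- arm$start + margin
      hi <- arm$end - margin - len + 1
      if (hi <= lo) next
      st <- floor(stats::runif(1, lo, hi))
      iv <- c(st, st + len - 1)
      if (!clashes(placed, arm$key, iv, margin)) {
        placed[[length(placed) + 1]] <<- list(key = arm$key, iv = iv)
        return(list(chrom = arm$chrom, start = iv[1], end = iv[2]))
      }
    }
    NULL
  }

  # terminal AI events: anchored at the telomeric end of a random arm
  for (i in seq_len(counts["tai"])) {
    ev <- NULL
    for (attempt in seq_len(100)) {
      arm <- arms[sample.int(nrow(arms), 1, prob = arms$len), , drop = FALSE]
      len <- floor(stats::runif(1, 5e6, 30e6))
      if (arm$len < len + margin) next
      iv <- if (arm$side == "p") c(arm$start, arm$start + len - 1) else c(arm$end - len + 1, arm$end)
      if (!clashes(placed, arm$key, iv, margin)) {
        placed[[length(placed) + 1]] <- list(key = arm$key, iv = iv)
        st <- if (stats::runif(1) < 0.5) c(2, 1) else c(3, 1)
        ev <- tibble::tibble(type = "tai", chrom = arm$chrom, start = iv[1], end = iv[2],
                             n_major = st[1], n_minor = st[2])
        break
      }
    }
    if (is.null(ev)) skip["tai"] <- skip["tai"] + 1L else events[[length(events) + 1]] <- ev
  }
  for (i in seq_len(counts["loh"])) {
    len <- floor(stats::runif(1, 16e6, 40e6))
    pos <- place_interstitial(len)
    if (is.null(pos)) skip["loh"] <- skip["loh"] + 1L
    else events[[length(events) + 1]] <- tibble::tibble(
      type = "loh", chrom = pos$chrom, start = pos$start, end = pos$end,
      n_major = 1, n_minor = 0)
  }
  for (i in seq_len(counts["lst"])) {
    len <- floor(stats::runif(1, 12e6, 25e6))
    pos <- place_interstitial(len)
    if (is.null(pos)) skip["lst"] <- skip["lst"] + 1L
    else events[[length(events) + 1]] <- tibble::tibble(
      type = "lst", chrom = pos$chrom, start = pos$start, end = pos$end,
      n_major = 2, n_minor = 2)
  }
  rng$restore()
  if (any(skip > 0)) {
    message("simulate_true_profile: skipped ", sum(skip),
            " unplaceable event(s); truth counts decremented")
  }
  events <- if (length(events)) dplyr::bind_rows(events) else
    tibble::tibble(type = character(), chrom = character(), start = numeric(),
                   end = numeric(), n_major = numeric(), n_minor = numeric())
  profile <- profile_from_events(build, events, sample_id)
  list(
    profile = profile,
    events = events,
    truth = list(seed = seed, archetype = archetype,
                 n_tai = unname(counts["tai"] - skip["tai"]),
                 n_loh = unname(counts["loh"] - skip["loh"]),
                 n_lst_breaks = 2L * unname(counts["lst"] - skip["lst"]))
  )
}

arm_table <- function(build) {
  chr <- build$chromosomes
  cen <- build$centromeres[match(chr$chrom, build$centromeres$chrom), ]
  p <- tibble::tibble(chrom = chr$chrom, side = "p", start = 1, end = cen$cen_start - 1)
  q <- tibble::tibble(chrom = chr$chrom, side = "q", start = cen$cen_end + 1, end = chr$length)
  arms <- rbind(p, q)
  arms$len <- arms$end - arms$start + 1
  arms$key <- paste(arms$chrom, arms$side)
  arms[arms$len > 0, , drop = FALSE]
}

clashes <- function(placed, key, iv, margin) {
  for (p in placed) {
    if (p$key != key) next
    if (iv[1] <= p$iv[2] + margin && p$iv[1] <= iv[2] + margin) return(TRUE)
  }
  FALSE
}

# Rebuild a full-genome segment table from an event list over a 1+1 diploid
# background. Events are non-overlapping by construction.
profile_from_events <- function(build, events, sample_id) {
  rows <- list()
  for (ci in seq_len(nrow(build$chromosomes))) {
    ch <- build$chromosomes$chrom[ci]
    len <- build$chromosomes$length[ci]
    ev <- events[events$chrom == ch, , drop = FALSE]
    ev <- ev[order(ev$start), , drop = FALSE]
    cursor <- 1
    for (i in seq_len(nrow(ev))) {
      if (ev$start[i] > cursor) {
        rows[[length(rows) + 1]] <- list(ch, cursor, ev$start[i] - 1, 1, 1)
      }
      rows[[length(rows) + 1]] <- list(ch, ev$start[i], ev$end[i], ev$n_major[i], ev$n_minor[i])
      cursor <- ev$end[i] + 1
    }
    if (cursor <= len) rows[[length(rows) + 1]] <- list(ch, cursor, len, 1, 1)
  }
  out <- tibble::tibble(
    sample = sample_id,
    chrom = vapply(rows, function(r) r[[1]], character(1)),
    start = vapply(rows, function(r) r[[2]], numeric(1)),
    end = vapply(rows, function(r) r[[3]], numeric(1)),
    n_major = vapply(rows, function(r) r[[4]], numeric(1)),
    n_minor = vapply(rows, function(r) r[[5]], numeric(1))
  )
  validate_segments(out)
}

#' Render a platform's view of a true segmentation
#'
#' Applies a [platform_model()] to the event list of a simulated truth:
#' each injected event is dropped with probability `p_miss_event` (its
#' footprint reverting to the diploid background), surviving event
#' boundaries are shifted by Gaussian jitter (clamped so ordering and
#' non-overlap are preserved), and spurious breakpoints are added as a
#' Poisson process along the genome — each perturbing the allele state over
#' a run of up to 3 Mb on one side of the breakpoint by incrementing the
#' major allele count.
#'
#' @param truth Result of [simulate_true_profile()].
#' @param model A [platform_model()].
#' @param seed Integer seed.
#' @param build A `genome_build` (the one the truth was simulated on).
#' @param sample_id Sample label for the rendered view.
#' @return A validated segment tibble.
#' @export
render_platform_view <- function(truth, model, seed = 1, build, sample_id = NULL) {
  stopifnot(inherits(model, "platform_model"))
  sample_id <- sample_id %||% paste0(truth$profile$sample[1], "_", model$label)
  rng <- local_rng(seed)
  ev <- truth$events
  if (nrow(ev) > 0 && model$p_miss_event > 0) {
    ev <- ev[stats::runif(nrow(ev)) >= model$p_miss_event, , drop = FALSE]
  }
  if (nrow(ev) > 0 && model$breakpoint_jitter_sd > 0) {
    # only true breakpoints move: a boundary at the chromosome end (the
    # telomeric edge of a terminal event) is the edge of the data, not a
    # breakpoint, and stays anchored
    len <- chrom_length(build, ev$chrom)
    at_start <- ev$start == 1
    at_end <- ev$end == len
    ev$start <- ev$start +
      ifelse(at_start, 0, round(stats::rnorm(nrow(ev), 0, model$breakpoint_jitter_sd)))
    ev$end <- ev$end +
      ifelse(at_end, 0, round(stats::rnorm(nrow(ev), 0, model$breakpoint_jitter_sd)))
    ev <- clamp_events(ev, build)
  }
  # spurious breakpoints: short perturbed-state runs at Poisson positions
  genome_mb <- sum(build$chromosomes$length) / 1e6
  n_spur <- stats::rpois(1, model$p_spurious_breakpoint * genome_mb / 100)
  if (n_spur > 0) {
    chr <- build$chromosomes
    for (i in seq_len(n_spur)) {
      ci <- sample.int(nrow(chr), 1, prob = chr$length)
      len <- floor(stats::runif(1, 5e5, 3e6))
      if (stats::runif(1) < model$frac_spurious_telomeric) {
        # subtelomeric coverage artefact: run anchored at a chromosome end
        iv <- if (stats::runif(1) < 0.5) c(1, len) else
          c(chr$length[ci] - len + 1, chr$length[ci])
      } else {
        bp <- sample.int(chr$length[ci] - 1, 1)
        left <- stats::runif(1) < 0.5  # which side of the breakpoint is perturbed
        iv <- if (left) c(max(1, bp - len + 1), bp) else
          c(bp + 1, min(chr$length[ci], bp + len))
      }
      ev <- rbind(ev, tibble::tibble(type = "spurious", chrom = chr$chrom[ci],
                                     start = iv[1], end = iv[2],
                                     n_major = NA_real_, n_minor = NA_real_))
    }
  }
  rng$restore()
  view_from_events(build, ev, sample_id)
}

clamp_events <- function(ev, build) {
  ev <- ev[order(ev$chrom, ev$start), , drop = FALSE]
  len <- chrom_length(build, ev$chrom)
  ev$start <- pmax(ev$start, 1)
  ev$end <- pmin(ev$end, len)
  ev <- ev[ev$start <= ev$end, , drop = FALSE]
  # resolve any jitter-induced overlap by trimming the later event
  if (nrow(ev) > 1) {
    for (i in 2:nrow(ev)) {
      if (ev$chrom[i] == ev$chrom[i - 1] && ev$start[i] <= ev$end[i - 1]) {
        ev$start[i] <- ev$end[i - 1] + 1
      }
    }
    ev <- ev[ev$start <= ev$end, , drop = FALSE]
  }
  ev
}

# Build the viewed profile: real events over the diploid background, then
# spurious perturbations overlaid on whatever state they land on.
view_from_events <- function(build, ev, sample_id) {
  real <- ev[is.na(ev$type) | ev$type != "spurious", , drop = FALSE]
  prof <- profile_from_events(build, real, sample_id)
  spur <- ev[!is.na(ev$type) & ev$type == "spurious", , drop = FALSE]
  if (nrow(spur) == 0) return(merge_adjacent(prof))
  for (i in seq_len(nrow(spur))) {
    prof <- overlay_perturbation(prof, spur$chrom[i], spur$start[i], spur$end[i])
  }
  merge_adjacent(validate_segments(prof))
}

# Increment n_major over [start, end] on one chromosome, splitting the
# underlying segments at the perturbation boundaries.
overlay_perturbation <- function(prof, chrom, start, end) {
  hit <- prof$chrom == chrom & prof$start <= end & prof$end >= start
  keep <- prof[!hit, , drop = FALSE]
  pieces <- list()
  for (i in which(hit)) {
    s <- prof[i, , drop = FALSE]
    if (s$start < start) {
      left <- s; left$end <- start - 1
      pieces[[length(pieces) + 1]] <- left
    }
    mid <- s
    mid$start <- max(s$start, start); mid$end <- min(s$end, end)
    mid$n_major <- mid$n_major + 1
    pieces[[length(pieces) + 1]] <- mid
    if (s$end > end) {
      right <- s; right$start <- end + 1
      pieces[[length(pieces) + 1]] <- right
    }
  }
  dplyr::arrange(dplyr::bind_rows(keep, dplyr::bind_rows(pieces)),
                 .data$sample, .data$chrom, .data$start)
}

#' Render a probe-level Log2/BAF track from a segment view
#'
#' Probes are laid every `probe_spacing` bp along each chromosome. Each
#' probe's Log2 ratio is `log2(total_copies / 2)` (floored at total 0.5)
#' plus Gaussian noise; its BAF is drawn around `n_minor / total`,
#' symmetrised at random about 0.5 (the assayed B allele is arbitrary),
#' with Gaussian noise and clamping to \[0, 1\].
#'
#' @param view Segment tibble (one sample).
#' @param model A [platform_model()].
#' @param seed Integer seed.
#' @return Probe-track tibble: `chrom`, `pos`, `log2`, `baf`.
#' @export
render_probe_track <- function(view, model, seed = 1) {
  stopifnot(inherits(model, "platform_model"))
  if (model$probe_spacing <= 0) stop("probe_spacing must be positive", call. = FALSE)
  rng <- local_rng(seed)
  out <- list()
  for (ch in unique(view$chrom)) {
    s <- view[view$chrom == ch, , drop = FALSE]
    pos <- seq(model$probe_spacing, max(s$end), by = model$probe_spacing)
    idx <- findInterval(pos, s$start)
    ok <- idx >= 1 & pos <= s$end[pmax(idx, 1)]
    pos <- pos[ok]; idx <- idx[ok]
    total <- s$n_major[idx] + s$n_minor[idx]
    log2v <- log2(pmax(total, 0.5) / 2) +
      if (model$log2_noise_sd > 0) stats::rnorm(length(pos), 0, model$log2_noise_sd) else 0
    baf0 <- ifelse(total > 0, s$n_minor[idx] / total, 0.5)
    flip <- stats::runif(length(pos)) < 0.5
    baf0 <- ifelse(flip, 1 - baf0, baf0)
    baf <- baf0 + if (model$baf_noise_sd > 0) stats::rnorm(length(pos), 0, model$baf_noise_sd) else 0
    out[[ch]] <- tibble::tibble(chrom = ch, pos = pos, log2 = log2v,
                                baf = pmin(pmax(baf, 0), 1))
  }
  rng$restore()
  dplyr::arrange(dplyr::bind_rows(out), .data$chrom, .data$pos)
}

#' Simulate a paired multi-platform cohort
#'
#' Draws `n_samples` ground-truth tumour profiles (a `deficient_fraction`
#' share from the HR-deficient archetype, assigned deterministically by
#' rounding), renders one view per platform model, and scores truths and
#' views. Per-sample and per-platform random streams are derived from the
#' single global seed, so the whole bundle is reproducible bit for bit.
#'
#' @param build A `genome_build`.
#' @param n_samples Number of tumours (>= 3).
#' @param deficient_fraction Fraction of HR-deficient archetypes.
#' @param models Named list of [platform_model()] objects (>= 2 for paired
#'   analyses).
#' @param seed Global integer seed.
#' @param params [scoring_params()] used for scoring.
#' @return List with `samples` (tibble: sample, archetype, truth counts),
#'   `truth_profiles`, `truth_scores`, `views` (named list of segment
#'   tibbles) and `scores` (named list of HRD result tibbles, samples
#'   aligned with the truth).
#' @export
simulate_cohort <- function(build, n_samples, deficient_fraction = 0.5,
                            models = platform_presets()[c("array", "wgs70x")],
                            seed = 1, params = scoring_params()) {
  stopifnot(n_samples >= 3, deficient_fraction >= 0, deficient_fraction <= 1)
  n_def <- round(n_samples * deficient_fraction)
  archetypes <- rep(c("hr_deficient", "hr_proficient"),
                    c(n_def, n_samples - n_def))
  truths <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    truths[[i]] <- simulate_true_profile(
      build, archetypes[i], seed = derive_seed(seed, i, 0),
      sample_id = sprintf("SYN%03d", i))
  }
  truth_profiles <- dplyr::bind_rows(lapply(truths, `[[`, "profile"))
  views <- list()
  for (pi in seq_along(models)) {
    model <- models[[pi]]
    v <- lapply(seq_len(n_samples), function(i) {
      render_platform_view(truths[[i]], model, seed = derive_seed(seed, i, pi),
                           build = build, sample_id = sprintf("SYN%03d", i))
    })
    views[[model$label]] <- dplyr::bind_rows(v)
  }
  samples <- tibble::tibble(
    sample = sprintf("SYN%03d", seq_len(n_samples)),
    archetype = archetypes,
    n_tai = vapply(truths, function(t) as.numeric(t$truth$n_tai), numeric(1)),
    n_loh = vapply(truths, function(t) as.numeric(t$truth$n_loh), numeric(1)),
    n_lst_breaks = vapply(truths, function(t) as.numeric(t$truth$n_lst_breaks), numeric(1))
  )
  list(
    samples = samples,
    truth_profiles = truth_profiles,
    truth_scores = score_hrd(truth_profiles, build, params),
    views = views,
    scores = lapply(views, score_hrd, build = build, params = params)
  )
}

# Sub-stream seeds derived from the global seed; kept below 2^31.
derive_seed <- function(seed, sample_index, platform_index) {
  as.integer((as.numeric(seed) * 48271 + sample_index * 10007 +
                platform_index * 97 + 12345) %% 2147483647)
}

# Scoped RNG: seed on creation, restore the caller's RNG state on $restore().
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(as.integer(seed %% 2147483647))
  list(restore = function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
}
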