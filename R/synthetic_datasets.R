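#' Generate a full synthetic community study
#'
#' Produces the three long-format assay tables the analysis modules
#' consume, with known ground truth:
#'
#' * **persistence**: every nonempty community composition inoculated at
#'   equal per-species density and left without resource replenishment;
#'   per-species plate-count densities recorded at weeks 2-4
#'   (replicated plate counts of each composition-week culture).
#' * **invasion**: every focal-by-resident-composition treatment, with
#'   the invader inoculated at a `dilution`-fold lower density than the
#'   resident community total (residents in equal ratios), grown for one
#'   batch; initial and final densities recorded.
#' * **supernatant**: each focal species grown for two days in fresh
#'   medium and in the cell-free supernatant of every species; the
#'   supernatant of species j rescales the focal's realised daily growth
#'   rate by `sigma[i, j]`.
#'
#' Lognormal plate-count noise and detection censoring are applied to
#' every measured (final) density. A single seed drives reproducible,
#' independent substreams per assay, so identical seeds give identical
#' datasets.
#'
#' @param params A [glv_params()] object (default
#'   [community_glv_params()]).
#' @param protocol A [batch_protocol()] object; `inoculum` sets the
#'   per-species persistence starting density.
#' @param noise A [noise_model()] object.
#' @param sigma Supernatant-effect ground-truth matrix (default
#'   [community_sigma()] for the five-species pool).
#' @param replicates Named list of replicate counts:
#'   `persistence` plate counts per composition-week (default 3),
#'   `invasion` replicate cultures per treatment (default 6),
#'   `supernatant` technical replicates per well (default 3).
#' @param seed Integer seed for the dataset (required).
#' @param weeks Persistence sampling weeks (default 2:4; week 1 is
#'   excluded from analysis because cultures have not yet equilibrated).
#' @param invasion_density Total resident inoculation density for the
#'   invasion assay (cfu/mL; default 2.5e7, dense normalised cultures
#'   diluted into fresh medium).
#' @param supernatant_n0 Starting density in the supernatant assay
#'   (cfu/mL, default 2.5e5).
#' @param assays Which tables to generate (subset of
#'   `c("persistence", "invasion", "supernatant")`).
#' @return Object of class `community_study`: a list with the requested
#'   data frames plus `params`, `protocol`, `noise`, `sigma` and `seed`.
#' @export
#' @examples
#' study <- generate_study_datasets(seed = 1, assays = "invasion")
#' nrow(unique(study$invasion[, c("focal", "residents")])) # 75 treatments
generate_study_datasets <- function(params = community_glv_params(),
                                    protocol = batch_protocol(),
                                    noise = noise_model(),
                                    sigma = NULL,
                                    replicates = list(),
                                    seed,
                                    weeks = 2:4,
                                    invasion_density = 2.5e7,
                                    supernatant_n0 = 2.5e5,
                                    assays = c("persistence", "invasion",
                                               "supernatant")) {
  stopifnot(inherits(params, "glv_params"), inherits(protocol, "batch_protocol"),
            inherits(noise, "noise_model"))
  if (missing(seed) || !is.numeric(seed)) {
    stop("a numeric seed is required for reproducible datasets", call. = FALSE)
  }
  assays <- match.arg(assays, several.ok = TRUE)
  reps <- modifyList(list(persistence = 3L, invasion = 6L, supernatant = 3L),
                     replicates)
  if (any(unlist(reps) < 1)) stop("replicate counts must be >= 1", call. = FALSE)
  species <- params$species
  if (is.null(sigma) && "supernatant" %in% assays) {
    if (length(species) == 5) {
      sigma <- community_sigma(species)
    } else {
      stop("sigma must be supplied for non-default pools", call. = FALSE)
    }
  }

  # one master seed -> independent fixed substreams per assay
  set.seed(as.integer(seed) %% .Machine$integer.max)
  substream <- sample.int(.Machine$integer.max - 1L, 3L)
  names(substream) <- c("persistence", "invasion", "supernatant")

  out <- list(params = params, protocol = protocol, noise = noise,
              sigma = sigma, seed = seed)

  if ("persistence" %in% assays) {
    set.seed(substream[["persistence"]])
    out$persistence <- simulate_persistence_assay(params, protocol, noise,
                                                  weeks, reps$persistence)
  }
  if ("invasion" %in% assays) {
    set.seed(substream[["invasion"]])
    out$invasion <- simulate_invasion_assay(params, protocol, noise,
                                            invasion_density, reps$invasion)
  }
  if ("supernatant" %in% assays) {
    set.seed(substream[["supernatant"]])
    out$supernatant <- simulate_supernatant_assay(params, noise, sigma,
                                                  supernatant_n0,
                                                  reps$supernatant)
  }
  class(out) <- "community_study"
  out
}

#' @export
print.community_study <- function(x, ...) {
  cat("Synthetic community study (seed ", x$seed, ")\n", sep = "")
  for (tab in c("persistence", "invasion", "supernatant")) {
    if (!is.null(x[[tab]])) cat("  ", tab, ": ", nrow(x[[tab]]), " records\n",
                                sep = "")
  }
  invisible(x)
}

# deterministic dynamics once per culture; noise per replicate plate count
simulate_persistence_assay <- function(params, protocol, noise, weeks, n_rep) {
  species <- params$species
  comps <- enumerate_compositions(species)
  inoc <- rep_len(protocol$inoculum, length(species))
  names(inoc) <- species
  rows <- vector("list", length(comps) * length(weeks))
  idx <- 0L
  for (comp in comps) {
    id <- composition_id(comp)
    n0 <- setNames(numeric(length(species)), species)
    n0[comp] <- inoc[comp]
    for (wk in weeks) {
      final <- integrate_batch(params, n0, days = wk * protocol$batch_days)
      reps <- lapply(seq_len(n_rep), function(rep) {
        data.frame(composition = id, species = comp, week = wk, replicate = rep,
                   density = apply_count_noise(unname(final[comp]), noise),
                   stringsAsFactors = FALSE)
      })
      idx <- idx + 1L
      rows[[idx]] <- do.call(rbind, reps)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

simulate_invasion_assay <- function(params, protocol, noise,
                                    invasion_density, n_rep) {
  species <- params$species
  design <- enumerate_invasion_design(species)
  rows <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    focal <- design$focal[i]
    residents <- split_composition(design$residents[i])
    n0 <- setNames(numeric(length(species)), species)
    n0[residents] <- invasion_density / length(residents)
    n0[focal] <- invasion_density / protocol$dilution
    final <- integrate_batch(params, n0, days = protocol$batch_days)
    present <- c(focal, residents)
    reps <- lapply(seq_len(n_rep), function(rep) {
      data.frame(focal = focal, residents = design$residents[i],
                 replicate = rep, species = present,
                 n0 = unname(n0[present]),
                 n1 = apply_count_noise(unname(final[present]), noise),
                 t = protocol$batch_days, stringsAsFactors = FALSE)
    })
    rows[[i]] <- do.call(rbind, reps)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

simulate_supernatant_assay <- function(params, noise, sigma, n0, n_rep,
                                       t_days = 2) {
  species <- params$species
  rows <- list()
  for (i in seq_along(species)) {
    focal <- species[i]
    # baseline: realised fresh-media growth over the assay from a 2-day
    # monoculture batch (saturation included)
    start <- setNames(numeric(length(species)), species)
    start[focal] <- n0
    n1_fresh <- integrate_batch(params, start, days = t_days)[focal]
    g_fresh <- log(n1_fresh / n0) / t_days
    sources <- c("fresh", species)
    for (src in sources) {
      g <- if (src == "fresh") g_fresh else g_fresh * sigma[focal, src]
      n1_true <- n0 * exp(g * t_days)
      rows[[length(rows) + 1L]] <- data.frame(
        focal = focal, source = src, replicate = seq_len(n_rep),
        n0 = n0, n1 = apply_count_noise(rep(n1_true, n_rep), noise),
        t = t_days, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write or read the study tables as TSV
#'
#' `write_study_tsv()` writes each generated table of a
#' `community_study` to `<dir>/<assay>.tsv`; `read_assay_tsv()` reads
#' one back. Plain tab-separated text keeps datasets diffable and
#' language-agnostic.
#'
#' @param study A `community_study` object.
#' @param dir Output directory (created if needed).
#' @return `write_study_tsv()` returns the written paths invisibly;
#'   `read_assay_tsv()` returns a data frame.
#' @export
write_study_tsv <- function(study, dir) {
  stopifnot(inherits(study, "community_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (tab in c("persistence", "invasion", "supernatant")) {
    if (is.null(study[[tab]])) next
    path <- file.path(dir, paste0(tab, ".tsv"))
    write.table(study[[tab]], path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' @rdname write_study_tsv
#' @param path Path to a TSV written by `write_study_tsv()`.
#' @export
read_assay_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
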