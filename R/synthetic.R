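#' Specification of a synthetic cohort
#'
#' Bundles the parameters of [simulate_cohort()] with validation. Defaults
#' describe a microarray-like cohort on the log2 scale: 2,000 genes, 20
#' controls and 20 cases, 50 disjoint gene sets of 30 genes, of which 5 are
#' planted up-regulated and 5 down-regulated with a maximum log2 shift of
#' 1.5 scaled by a linear per-case severity gradient, per-cell noise of
#' 0.3, and baseline log2 intensities drawn from Normal(7, 1) floored at 0.
#'
#' @param n_genes Number of genes.
#' @param n_controls,n_cases Group sizes.
#' @param n_sets,set_size Number of (disjoint) gene sets and their size;
#'   `n_sets * set_size` must not exceed `n_genes` unless `overlap = TRUE`.
#' @param n_planted_up,n_planted_down How many sets receive a positive /
#'   negative expression shift in cases.
#' @param effect Log2 shift at maximum severity (> 0 when any set is
#'   planted).
#' @param severity `"linear"` (case `j` of `n` has severity `j/n`) or
#'   `"constant"` (all cases at severity 1).
#' @param noise_sd Per-cell Gaussian noise standard deviation (log2 units).
#' @param baseline_mean,baseline_sd Per-gene baseline log2 intensity
#'   distribution.
#' @param overlap Draw each set independently from the gene pool instead of
#'   assigning disjoint blocks (ground-truth FDR accounting then becomes
#'   ambiguous; default `FALSE`).
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A `simulation_spec` list, validated.
#' @export
simulation_spec <- function(n_genes = 2000L, n_controls = 20L,
                            n_cases = 20L, n_sets = 50L, set_size = 30L,
                            n_planted_up = 5L, n_planted_down = 5L,
                            effect = 1.5, severity = c("linear", "constant"),
                            noise_sd = 0.3, baseline_mean = 7,
                            baseline_sd = 1, overlap = FALSE, seed = 1L) {
  severity <- match.arg(severity)
  spec <- list(n_genes = as.integer(n_genes),
               n_controls = as.integer(n_controls),
               n_cases = as.integer(n_cases),
               n_sets = as.integer(n_sets),
               set_size = as.integer(set_size),
               n_planted_up = as.integer(n_planted_up),
               n_planted_down = as.integer(n_planted_down),
               effect = effect, severity = severity, noise_sd = noise_sd,
               baseline_mean = baseline_mean, baseline_sd = baseline_sd,
               overlap = isTRUE(overlap), seed = as.integer(seed))
  stopifnot(spec$n_genes >= 1L, spec$n_controls >= 1L, spec$n_cases >= 1L,
            spec$n_sets >= 1L, spec$set_size >= 1L,
            spec$n_planted_up + spec$n_planted_down <= spec$n_sets,
            spec$effect >= 0, spec$noise_sd > 0, spec$baseline_sd >= 0)
  if (!spec$overlap && spec$n_sets * spec$set_size > spec$n_genes) {
    stop("disjoint sets need n_sets * set_size <= n_genes", call. = FALSE)
  }
  structure(spec, class = "simulation_spec")
}

# run code under a seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Simulate a cohort with planted gene sets and a severity gradient
#'
#' Generates a log2-scale expression matrix, a gene-set collection, a
#' phenotype table and the ground truth needed for power, FDR and
#' ordering-recovery studies. Baseline expression per gene is
#' Normal(`baseline_mean`, `baseline_sd`); each cell adds
#' Normal(0, `noise_sd`) noise. Genes in a planted-up set gain
#' `+effect * severity_j` in case `j` (planted-down lose the same amount),
#' where `severity_j = j / n_cases` under the linear gradient, so later
#' cases are progressively more aberrant — emulating the amplification of
#' expression change with disease progression. All values are floored at 0
#' to stay valid log-scale input.
#'
#' @param spec A [simulation_spec()].
#' @return A list: `expression` (tibble, `gene` + sample columns), `sets`
#'   (tibble `set`/`description`/`gene`), `phenotypes` (tibble
#'   `sample`/`group`), and `truth` — a list with `planted_up`,
#'   `planted_down` (set names) and `severity` (tibble `sample`/`severity`
#'   for the cases).
#' @examples
#' sim <- simulate_cohort(simulation_spec(seed = 42))
#' dim(sim$expression)
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(spec$seed, {
    pad <- function(prefix, i, n) {
      sprintf("%s_%0*d", prefix, nchar(as.character(n)), i)
    }
    genes <- pad("g", seq_len(spec$n_genes), spec$n_genes)
    samples <- c(pad("ctrl", seq_len(spec$n_controls), spec$n_controls),
                 pad("case", seq_len(spec$n_cases), spec$n_cases))
    n_samp <- length(samples)
    set_names <- pad("set", seq_len(spec$n_sets), spec$n_sets)

    pool <- sample(genes)
    members <- if (spec$overlap) {
      lapply(seq_len(spec$n_sets), \(i) sample(genes, spec$set_size))
    } else {
      split(pool[seq_len(spec$n_sets * spec$set_size)],
            rep(seq_len(spec$n_sets), each = spec$set_size))
    }
    names(members) <- set_names
    planted_up <- set_names[seq_len(spec$n_planted_up)]
    planted_down <- set_names[spec$n_planted_up +
                                seq_len(spec$n_planted_down)]

    baseline <- pmax(stats::rnorm(spec$n_genes, spec$baseline_mean,
                                  spec$baseline_sd), 0)
    m <- baseline +
      matrix(stats::rnorm(spec$n_genes * n_samp, 0, spec$noise_sd),
             spec$n_genes, n_samp)
    dimnames(m) <- list(genes, samples)

    sev <- if (spec$severity == "linear") {
      seq_len(spec$n_cases) / spec$n_cases
    } else {
      rep(1, spec$n_cases)
    }
    case_cols <- spec$n_controls + seq_len(spec$n_cases)
    up_genes <- genes %in% unlist(members[planted_up])
    down_genes <- genes %in% unlist(members[planted_down])
    shift <- outer(rep(0, spec$n_genes), rep(0, spec$n_cases))
    if (length(planted_up) > 0L) {
      shift[up_genes, ] <- rep(spec$effect * sev, each = sum(up_genes))
    }
    if (length(planted_down) > 0L) {
      shift[down_genes, ] <- rep(-spec$effect * sev, each = sum(down_genes))
    }
    m[, case_cols] <- m[, case_cols] + shift
    m <- pmax(m, 0)

    list(
      expression = values_to_tbl(m, "gene"),
      sets = purrr::imap_dfr(members, \(g, nm) tibble::tibble(
        set = nm, description = "synthetic", gene = g
      )),
      phenotypes = tibble::tibble(
        sample = samples,
        group = rep(c("control", "case"),
                    c(spec$n_controls, spec$n_cases))
      ),
      truth = list(
        planted_up = planted_up,
        planted_down = planted_down,
        severity = tibble::tibble(sample = samples[case_cols],
                                  severity = sev)
      )
    )
  })
}

#' Simulate a similarity trace fixture
#'
#' Generates idealized clustering traces for exercising [segment_trace()]:
#' `"linear"` is a decreasing line with small Gaussian noise (no curvature
#' change, hence one class); `"two_arc"` concatenates a concave quadratic
#' arc and a convex one joined at `floor(n/2)`, so the curvature flips sign
#' at a known junction.
#'
#' @param kind `"linear"` or `"two_arc"`.
#' @param n Trace length (>= 5).
#' @param seed Integer seed for the noise.
#' @param noise_sd Noise standard deviation (default 0.02; arcs have unit
#'   amplitude).
#' @return Numeric trace of length `n`, with attribute `junction` (the
#'   true curvature-change rank; `NA` for `"linear"`).
#' @export
simulate_trace <- function(kind = c("linear", "two_arc"), n, seed = 1L,
                           noise_sd = 0.02) {
  kind <- match.arg(kind)
  if (n < 5L) stop("trace length must be >= 5", call. = FALSE)
  with_seed(seed, {
    r <- seq_len(n)
    if (kind == "linear") {
      y <- 10 - 0.3 * r + stats::rnorm(n, 0, noise_sd)
      junction <- NA_integer_
    } else {
      junction <- as.integer(floor(n / 2))
      y <- numeric(n)
      left <- r <= junction
      # concave arc on [1, junction], convex arc on [junction, n],
      # both of unit amplitude and zero at their endpoints
      y[left] <- -4 * (r[left] - 1) * (r[left] - junction) /
        (junction - 1)^2
      y[!left] <- 4 * (r[!left] - junction) * (r[!left] - n) / (n - junction)^2
      y <- y + stats::rnorm(n, 0, noise_sd)
    }
    structure(y, junction = junction)
  })
}
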