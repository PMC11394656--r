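#' Default class mixtures for the two seasonal conditions
#'
#' The breeding-season (BSB) testis libraries are dominated by piRNA
#' (fraction 0.678, the midpoint of the reported 65.11-70.46% range), while
#' non-breeding (NBS) libraries carry far less piRNA (0.237, midpoint of
#' 22.13-25.24%) with miRNA taking most of the remaining mass.
#'
#' @return Named list with one named fraction vector per condition.
#' @export
default_class_fractions <- function() {
  list(
    BSB = c(piRNA = 0.678, miRNA = 0.180, rRNA = 0.060, tRNA = 0.040,
            snRNA = 0.020, snoRNA = 0.012, other = 0.010),
    NBS = c(piRNA = 0.237, miRNA = 0.450, rRNA = 0.130, tRNA = 0.090,
            snRNA = 0.045, snoRNA = 0.028, other = 0.020)
  )
}

#' Default piRNA length distribution
#'
#' Supported on 27-32 nt with the mode at 30 nt, matching the unimodal
#' testis piRNA length profile this package emulates.
#'
#' @return Named numeric vector of probabilities over lengths 27..32.
#' @export
default_pirna_length_dist <- function() {
  c(`27` = 0.05, `28` = 0.10, `29` = 0.20, `30` = 0.35, `31` = 0.20,
    `32` = 0.10)
}

#' Configuration for the synthetic small-RNA data generator
#'
#' Bundles every tunable of the simulator: per-condition ncRNA class
#' mixtures, the piRNA length distribution, the strength of the 1U and 10A
#' base biases, the fraction of piRNA reads emitted as ping-pong secondary
#' partners, genomic-origin fractions, negative-binomial count-matrix
#' parameters, and the differential-expression design.
#'
#' @param class_fractions Named list `condition -> named fraction vector`
#'   over the classes miRNA, rRNA, tRNA, snRNA, snoRNA, piRNA, other; each
#'   vector must sum to 1.
#' @param pirna_length_dist Named probability vector over piRNA lengths;
#'   support must lie within 27..32 nt.
#' @param mirna_length_mode Modal mature-miRNA length in nt (default 22).
#' @param q1U Probability that a piRNA read carries U at position 1.
#' @param q10A Probability that a piRNA read carries A at position 10
#'   (for ping-pong pairs the two biases are coupled through the duplex
#'   geometry; see the methods vignette).
#' @param pingpong_fraction Fraction of piRNA reads emitted as secondary
#'   (ping-pong) partners. Secondaries are emitted in pairs with their
#'   primary, so the realised fraction is capped at 0.5.
#' @param origin_fractions Named fraction vector over genomic categories
#'   `repeat`, `gene`, `other`; must sum to 1.
#' @param nb_mean,nb_dispersion Negative-binomial mean and dispersion
#'   (variance = mean + dispersion * mean^2) for simulated count matrices.
#' @param de_fraction Fraction of piRNAs with a true condition effect.
#' @param de_up_share Share of true effects that are up in BSB (default
#'   0.886, i.e. 86433 of 97580).
#' @param effect_log2fc True |log2 fold change| for affected piRNAs.
#' @param n_reads Library size (total read copies per library).
#' @param n_replicates Replicates per condition in count matrices.
#' @param seed Default integer seed used when an operation is not given one.
#'
#' @return Object of class `generator_config`.
#' @examples
#' cfg <- generator_config(n_reads = 1000)
#' cfg$class_fractions$BSB[["piRNA"]]
#' @export
generator_config <- function(class_fractions = default_class_fractions(),
                             pirna_length_dist = default_pirna_length_dist(),
                             mirna_length_mode = 22L,
                             q1U = 0.85,
                             q10A = 0.85,
                             pingpong_fraction = 0.3,
                             origin_fractions = c(`repeat` = 0.15,
                                                  gene = 0.01, other = 0.84),
                             nb_mean = 500,
                             nb_dispersion = 0.05,
                             de_fraction = 0.2,
                             de_up_share = 0.886,
                             effect_log2fc = 2,
                             n_reads = 200000L,
                             n_replicates = 3L,
                             seed = 1L) {
  stop_if(!is.list(class_fractions) || length(class_fractions) == 0L,
          "class_fractions must be a non-empty named list of conditions")
  for (cond in names(class_fractions)) {
    check_fraction_map(class_fractions[[cond]],
                       sprintf("class_fractions[%s]", cond))
  }
  check_fraction_map(pirna_length_dist, "pirna_length_dist")
  lens <- as.integer(names(pirna_length_dist))
  stop_if(any(is.na(lens)) || any(lens < 27L) || any(lens > 32L),
          "pirna_length_dist support must lie within 27..32 nt")
  check_prob(q1U, "q1U")
  check_prob(q10A, "q10A")
  check_prob(pingpong_fraction, "pingpong_fraction")
  check_prob(de_fraction, "de_fraction")
  check_prob(de_up_share, "de_up_share")
  check_fraction_map(origin_fractions, "origin_fractions")
  stop_if(!setequal(names(origin_fractions), c("repeat", "gene", "other")),
          "origin_fractions must be over {repeat, gene, other}")
  stop_if(nb_mean <= 0, "nb_mean must be > 0")
  stop_if(nb_dispersion <= 0, "nb_dispersion must be > 0")
  stop_if(effect_log2fc < 0, "effect_log2fc must be >= 0")
  stop_if(n_reads < 1, "n_reads must be >= 1")
  stop_if(n_replicates < 2, "n_replicates must be >= 2")
  structure(list(
    class_fractions = class_fractions,
    pirna_length_dist = pirna_length_dist,
    mirna_length_mode = as.integer(mirna_length_mode),
    q1U = q1U, q10A = q10A,
    pingpong_fraction = pingpong_fraction,
    origin_fractions = origin_fractions,
    nb_mean = nb_mean, nb_dispersion = nb_dispersion,
    de_fraction = de_fraction, de_up_share = de_up_share,
    effect_log2fc = effect_log2fc,
    n_reads = as.integer(n_reads),
    n_replicates = as.integer(n_replicates),
    seed = as.integer(seed)
  ), class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic small-RNA generator configuration\n")
  for (cond in names(x$class_fractions)) {
    f <- x$class_fractions[[cond]]
    cat(sprintf("  %s: piRNA %.3f, miRNA %.3f, other classes %.3f\n",
                cond, f[["piRNA"]], f[["miRNA"]],
                1 - f[["piRNA"]] - f[["miRNA"]]))
  }
  cat(sprintf("  piRNA lengths %s nt (mode %s), q1U=%.2f q10A=%.2f, ping-pong %.2f\n",
              paste(range(as.integer(names(x$pirna_length_dist))),
                    collapse = "-"),
              names(which.max(x$pirna_length_dist)), x$q1U, x$q10A,
              x$pingpong_fraction))
  cat(sprintf("  origins: repeat %.2f / gene %.2f / other %.2f\n",
              x$origin_fractions[["repeat"]], x$origin_fractions[["gene"]],
              x$origin_fractions[["other"]]))
  cat(sprintf("  counts: NB(mean=%g, disp=%g), DE fraction %.2f (up share %.3f, |log2FC|=%g), %d x 2 replicates\n",
              x$nb_mean, x$nb_dispersion, x$de_fraction, x$de_up_share,
              x$effect_log2fc, x$n_replicates))
  cat(sprintf("  library size %d reads, seed %d\n", x$n_reads, x$seed))
  invisible(x)
}

#' Write / read a generator configuration as YAML
#'
#' @param config A [generator_config()] object.
#' @param path File path.
#' @return `read_config_yaml` returns a `generator_config`;
#'   `write_config_yaml` returns `path` invisibly.
#' @export
write_config_yaml <- function(config, path) {
  stop_if(!inherits(config, "generator_config"),
          "config must be a generator_config")
  x <- unclass(config)
  x$class_fractions <- lapply(x$class_fractions, as.list)
  x$pirna_length_dist <- as.list(x$pirna_length_dist)
  x$origin_fractions <- as.list(x$origin_fractions)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  x$class_fractions <- lapply(x$class_fractions, unlist)
  x$pirna_length_dist <- unlist(x$pirna_length_dist)
  x$origin_fractions <- unlist(x$origin_fractions)
  do.call(generator_config, x)
}
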