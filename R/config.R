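#' Pipeline configuration
#'
#' A single YAML schema holds every tunable: classifier intervals, splice
#' boundaries, alignment scoring, clash cutoff and the RMSD match
#' threshold. The packaged default is returned by [default_config()].
#'
#' @name config
NULL

#' Load the packaged default configuration
#'
#' @return validated config list.
#' @export
default_config <- function() {
  read_config(system.file("extdata", "default_config.yaml", package = "dfgout"))
}

#' Read and validate a YAML configuration
#'
#' @param path YAML file.
#' @return validated config list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

.check_interval <- function(x, name) {
  x <- suppressWarnings(as.numeric(unlist(x)))
  if (length(x) != 2 || anyNA(x) || x[1] > x[2]) {
    stop(sprintf("malformed interval %s: [%s]", name,
                 paste(x, collapse = ", ")), call. = FALSE)
  }
  x
}

.intervals_overlap <- function(a, b) a[1] <= b[2] && b[1] <= a[2]

#' Validate a configuration list
#'
#' Checks interval well-formedness, `d_in_max < d_out_min`, the P-loop
#' minimum-conditions range, and that no two A-loop class boxes overlap
#' (which guarantees that at most one A-loop class can match).
#'
#' @param cfg config list.
#' @return the config, invisibly classed `dfgout_config`.
#' @export
validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  cfg$dfg$in_interval <- .check_interval(cfg$dfg$in_interval,
                                         "dfg$in_interval")
  cfg$dfg$out_interval <- .check_interval(cfg$dfg$out_interval,
                                          "dfg$out_interval")
  if (!(cfg$alphac$d_in_max < cfg$alphac$d_out_min)) {
    stop("alphac: d_in_max must be < d_out_min")
  }
  mc <- cfg$ploop$min_conditions
  if (!is.numeric(mc) || mc < 1 || mc > 4) {
    stop("ploop$min_conditions must be in 1..4")
  }
  pfeat <- c("psi_gmotif_m1", "psi_gmotif_p1", "xi_gmotif_p1_p2",
             "d_phi__hrd_p4")
  for (cl in names(cfg$ploop$classes)) {
    for (f in pfeat) {
      cfg$ploop$classes[[cl]][[f]] <-
        .check_interval(cfg$ploop$classes[[cl]][[f]],
                        sprintf("ploop$%s$%s", cl, f))
    }
  }
  afeat <- c("xi_dfg_m1_d", "xi_dfg_f_g", "d_hrd_m4__dfg_p3")
  acl <- names(cfg$aloop$classes)
  for (cl in acl) {
    for (f in afeat) {
      cfg$aloop$classes[[cl]][[f]] <-
        .check_interval(cfg$aloop$classes[[cl]][[f]],
                        sprintf("aloop$%s$%s", cl, f))
    }
  }
  if (length(acl) > 1) {
    for (i in seq_len(length(acl) - 1)) {
      for (j in seq((i + 1), length(acl))) {
        boxes_overlap <- all(vapply(afeat, function(f) {
          .intervals_overlap(cfg$aloop$classes[[acl[i]]][[f]],
                             cfg$aloop$classes[[acl[j]]][[f]])
        }, logical(1)))
        if (boxes_overlap) {
          stop(sprintf(
            "aloop class boxes overlap: %s and %s (classes must be mutually exclusive)",
            acl[i], acl[j]))
        }
      }
    }
  }
  b <- cfg$boundaries
  if (!(b$nlobe_start < b$nlobe_end && b$nlobe_end < b$aloop_start &&
        b$aloop_start < b$aloop_end)) {
    stop("boundaries must satisfy nlobe_start < nlobe_end < aloop_start < aloop_end")
  }
  if (!(b$aloop_start <= 184 && b$aloop_end >= 186)) {
    stop("aloop range must contain the DFG motif (reference IDs 184-186)")
  }
  structure(cfg, class = c("dfgout_config", "list"))
}

# cheap deterministic content hash for manifests (FNV-1a over the
# serialized config; not cryptographic, just change detection)
.config_hash <- function(cfg) {
  s <- utf8ToInt(paste(deparse(unclass(cfg)), collapse = "\n"))
  h <- 2166136261
  for (b in s) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", h)
}
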