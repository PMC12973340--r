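#' Specification of a synthetic FC/SC cohort
#'
#' Defines the study conditions emulated by the generator: healthy functional
#' connectivity with network block structure and bounded values, sparse
#' non-negative structural connectivity coupled to FC, inter-subject
#' variability, and glioma subjects whose SC is attenuated on edges incident
#' to the tumor while FC is perturbed in a network distal to the lesion
#' (SC damage proximal, FC damage distal). Defaults mirror the reference
#' study design: a 210-parcel scheme, 87/37/31 healthy train/validation/test
#' subjects, and 7 fine-tuning + 3 fine-tuning-validation + 31 test patients.
#'
#' @param parcel_count Number of parcels (210 uses the Schaefer +
#'   subcortical scheme; other even values use [toy_parcellation()]).
#' @param networks_per_hemisphere Networks per hemisphere for toy schemes.
#' @param n_train,n_val,n_test Healthy split sizes.
#' @param n_finetune_train,n_finetune_val,n_patient_test Glioma split sizes.
#' @param fc_within,fc_between Mean within-/between-network FC of the group
#'   template.
#' @param fc_template_sd Edgewise spread of template FC around the block
#'   means.
#' @param subject_noise_sd SD of the additive symmetric FC noise per subject.
#' @param sc_density Expected fraction of nonzero SC edges.
#' @param sc_meanlog,sc_sdlog Log-normal parameters of nonzero streamline
#'   counts.
#' @param sc_jitter_sd SD of the multiplicative log-normal SC jitter per
#'   subject.
#' @param tumor_radius,edema_radius Lesion extents in parcel-adjacency hops.
#' @param sc_effect Multiplicative attenuation of SC edges incident to tumor
#'   parcels, in `[0, 1]` (1 = no effect).
#' @param fc_effect_distal Additive FC shift applied to edges incident to the
#'   designated distal network.
#' @param finetune_sc_effect,finetune_fc_effect Milder effects used for the
#'   fine-tuning patients (chosen for limited abnormality, as transfer
#'   learning requires).
#' @param lesion_seed_parcel Optional fixed lesion seed parcel id; by default
#'   each glioma subject draws one at random.
#' @param total_streamlines Tractogram size used when converting counts.
#' @param volume_per_parcel mm^3 assigned per lesioned parcel (volumes are
#'   parcel-count proxies; only their ordering is meaningful).
#' @param seed Base seed for the whole cohort.
#' @return A list of class `connvae_sim_spec`.
#' @export
simulation_spec <- function(parcel_count = 210,
                            networks_per_hemisphere = 5,
                            n_train = 87, n_val = 37, n_test = 31,
                            n_finetune_train = 7, n_finetune_val = 3,
                            n_patient_test = 31,
                            fc_within = 0.6, fc_between = 0.1,
                            fc_template_sd = 0.05,
                            subject_noise_sd = 0.05,
                            sc_density = 0.25,
                            sc_meanlog = log(2000), sc_sdlog = 1,
                            sc_jitter_sd = 0.2,
                            tumor_radius = 1, edema_radius = 2,
                            sc_effect = 0.3, fc_effect_distal = 0.15,
                            finetune_sc_effect = 0.85,
                            finetune_fc_effect = 0.03,
                            lesion_seed_parcel = NULL,
                            total_streamlines = 1e7,
                            volume_per_parcel = 1500,
                            seed = 1) {
  stopifnot(fc_within > -1, fc_within < 1, fc_between > -1, fc_between < 1,
            sc_effect >= 0, sc_effect <= 1,
            finetune_sc_effect >= 0, finetune_sc_effect <= 1,
            sc_density > 0, sc_density <= 1,
            n_train > 0, n_val > 0, n_test > 0)
  if (fc_within <= fc_between) {
    warn("fc_within <= fc_between: template has no block structure")
  }
  scheme <- if (parcel_count == 210) schaefer_aal_parcellation()
            else toy_parcellation(parcel_count, networks_per_hemisphere)
  structure(
    list(parcel_count = parcel_count, scheme = scheme,
         n_train = n_train, n_val = n_val, n_test = n_test,
         n_finetune_train = n_finetune_train,
         n_finetune_val = n_finetune_val,
         n_patient_test = n_patient_test,
         fc_within = fc_within, fc_between = fc_between,
         fc_template_sd = fc_template_sd,
         subject_noise_sd = subject_noise_sd,
         sc_density = sc_density, sc_meanlog = sc_meanlog,
         sc_sdlog = sc_sdlog, sc_jitter_sd = sc_jitter_sd,
         tumor_radius = tumor_radius, edema_radius = edema_radius,
         sc_effect = sc_effect, fc_effect_distal = fc_effect_distal,
         finetune_sc_effect = finetune_sc_effect,
         finetune_fc_effect = finetune_fc_effect,
         lesion_seed_parcel = lesion_seed_parcel,
         total_streamlines = total_streamlines,
         volume_per_parcel = volume_per_parcel,
         seed = seed),
    class = "connvae_sim_spec")
}

clip_open <- function(m, eps = 1e-4) pmin(pmax(m, -1 + eps), 1 - eps)

# symmetric zero-diagonal matrix of N(0, sd) noise
sym_noise <- function(p, sd) {
  z <- matrix(0, p, p)
  z[upper.tri(z)] <- rnorm(p * (p - 1) / 2, sd = sd)
  z + t(z)
}

#' Generate the group-level FC and SC templates
#'
#' FC template: block-structured around `fc_within` / `fc_between`, symmetric,
#' zero diagonal, strictly inside (-1, 1). SC template: sparse non-negative
#' streamline counts; the probability that an edge is nonzero increases
#' monotonically with the template FC rank (structure-function coupling) while
#' averaging `sc_density`; nonzero counts are log-normal.
#'
#' @param spec A `connvae_sim_spec`.
#' @return List with `fc` (template FC), `sc_counts` (integer counts),
#'   `sc` (counts / total_streamlines) and the `scheme`.
#' @export
simulate_group_template <- function(spec) {
  stopifnot(inherits(spec, "connvae_sim_spec"))
  set.seed(derive_seed(spec$seed, "template"))
  scheme <- spec$scheme
  p <- n_parcels(scheme)
  same_net <- outer(scheme$network_key, scheme$network_key, "==")
  mu <- ifelse(same_net, spec$fc_within, spec$fc_between)
  fc <- mu + sym_noise(p, spec$fc_template_sd)
  fc <- clip_open((fc + t(fc)) / 2)
  diag(fc) <- 0

  ut <- upper.tri(fc)
  n_edges <- sum(ut)
  # monotone coupling: edge presence probability proportional to FC rank,
  # mean equal to sc_density
  r <- rank(fc[ut], ties.method = "average") / (n_edges + 1)
  prob <- pmin(1, 2 * spec$sc_density * r)
  present <- runif(n_edges) < prob
  counts_ut <- ifelse(present,
                      pmax(2, round(rlnorm(n_edges, spec$sc_meanlog,
                                           spec$sc_sdlog))),
                      0)
  sc_counts <- matrix(0, p, p)
  sc_counts[ut] <- counts_ut
  sc_counts <- sc_counts + t(sc_counts)
  list(fc = fc, sc_counts = sc_counts,
       sc = sc_counts / spec$total_streamlines, scheme = scheme)
}

#' Simulate one healthy subject
#'
#' Subject FC is the template plus symmetric Gaussian noise, re-clipped to
#' (-1, 1); subject SC applies edgewise multiplicative log-normal jitter to
#' the template counts (zeros stay zero).
#'
#' @param templates Output of [simulate_group_template()].
#' @param spec A `connvae_sim_spec`.
#' @param subject_seed Integer seed for this subject.
#' @param subject_id,split Identifiers stored in the record.
#' @return List with `fc`, `sc_counts`, and `record` (one-row cohort tibble).
#' @export
simulate_healthy_subject <- function(templates, spec, subject_seed,
                                     subject_id = "sub", split = "train") {
  set.seed(subject_seed)
  p <- nrow(templates$fc)
  fc <- templates$fc
  if (spec$subject_noise_sd > 0) {
    fc <- clip_open(fc + sym_noise(p, spec$subject_noise_sd))
  }
  diag(fc) <- 0
  sc_counts <- templates$sc_counts
  if (spec$sc_jitter_sd > 0) {
    jit <- exp(sym_noise(p, spec$sc_jitter_sd))
    sc_counts <- round(sc_counts * jit)
  }
  record <- subject_records(tibble(
    subject_id = subject_id, cohort = "healthy", split = split,
    tumor_fraction = list(rep(0, p)), edema_fraction = list(rep(0, p))
  ), scheme = spec$scheme)
  list(fc = conn_matrix(fc, "FC", subject_id),
       sc_counts = conn_matrix(sc_counts, "SC_counts", subject_id),
       record = record)
}

# parcel adjacency used for lesion growth: parcels sharing a hemisphere-
# specific network are adjacent, plus a ring ordering within each hemisphere
# (a geometry-free stand-in for spatial neighborhood)
parcel_adjacency <- function(scheme) {
  p <- n_parcels(scheme)
  adj <- outer(scheme$network_key, scheme$network_key, "==")
  for (h in c("left", "right")) {
    idx <- which(scheme$hemisphere == h)
    k <- length(idx)
    nxt <- idx[c(2:k, 1)]
    adj[cbind(idx, nxt)] <- TRUE
    adj[cbind(nxt, idx)] <- TRUE
  }
  diag(adj) <- FALSE
  adj
}

# breadth-first hop distances from a seed parcel
hop_distances <- function(adj, start) {
  p <- nrow(adj)
  d <- rep(Inf, p)
  d[start] <- 0
  frontier <- start
  hop <- 0
  while (length(frontier)) {
    hop <- hop + 1
    reach <- which(colSums(adj[frontier, , drop = FALSE]) > 0)
    nbrs <- reach[is.infinite(d[reach])]
    if (!length(nbrs)) break
    d[nbrs] <- hop
    frontier <- nbrs
  }
  d
}

# pick the network used for the distal FC perturbation: the contralateral
# network whose parcels are farthest (in hops) from the lesion seed
pick_distal_network <- function(scheme, dists, lesion_hemisphere) {
  contra <- setdiff(c("left", "right"), lesion_hemisphere)
  cand <- networks(scheme) |> filter(.data$hemisphere == contra)
  far <- vapply(cand$network_key, function(k)
    mean(dists[scheme$network_key == k]), numeric(1))
  cand$network_key[which.max(far)]
}

#' Simulate one glioma subject with known ground truth
#'
#' The tumor core is the lesion seed parcel plus all parcels within
#' `tumor_radius` hops on the parcel adjacency graph; an edema ring extends to
#' `edema_radius` hops. SC edges incident to tumor parcels are multiplied by
#' `sc_effect`; FC edges incident to the designated distal network (in the
#' contralateral hemisphere) are shifted by `fc_effect_distal` and re-clipped.
#' Lesion volumes are parcel-count proxies.
#'
#' @inheritParams simulate_healthy_subject
#' @param sc_effect,fc_effect_distal Optional overrides of the spec effects
#'   (used for the milder fine-tuning patients).
#' @return List with `fc`, `sc_counts`, `record`, and `ground_truth` (list
#'   with `tumor_parcels`, `edema_parcels`, `sc_perturbed`, `fc_perturbed`,
#'   `distal_network`).
#' @export
simulate_glioma_subject <- function(templates, spec, subject_seed,
                                    subject_id = "pat", split = "test",
                                    sc_effect = spec$sc_effect,
                                    fc_effect_distal = spec$fc_effect_distal) {
  healthy <- simulate_healthy_subject(templates, spec, subject_seed,
                                      subject_id, split)
  scheme <- spec$scheme
  p <- n_parcels(scheme)
  set.seed(derive_seed(subject_seed, "lesion"))
  seed_parcel <- if (!is.null(spec$lesion_seed_parcel)) {
    match(spec$lesion_seed_parcel, scheme$parcel_id)
  } else {
    sample.int(p, 1)
  }
  if (is.na(seed_parcel)) {
    abort("lesion_seed_parcel not in scheme", class = "connvae_format_error")
  }
  lesion_hemisphere <- scheme$hemisphere[seed_parcel]
  adj <- parcel_adjacency(scheme)
  d <- hop_distances(adj, seed_parcel)
  tumor <- which(d <= spec$tumor_radius)
  edema <- setdiff(which(d <= spec$edema_radius), tumor)
  hemi_size <- sum(scheme$hemisphere == lesion_hemisphere)
  if (length(tumor) + length(edema) >= hemi_size) {
    abort("lesion exceeds hemisphere", class = "connvae_format_error")
  }

  fc <- unclass(healthy$fc)
  sc_counts <- unclass(healthy$sc_counts)
  null_effect <- (sc_effect == 1 && fc_effect_distal == 0)

  # SC attenuation proximal to the lesion
  if (sc_effect < 1) {
    touched <- matrix(FALSE, p, p)
    touched[tumor, ] <- TRUE
    touched[, tumor] <- TRUE
    sc_counts[touched] <- round(sc_counts[touched] * sc_effect)
  }
  # FC perturbation distal to the lesion
  distal_key <- pick_distal_network(scheme, d, lesion_hemisphere)
  distal <- which(scheme$network_key == distal_key)
  if (fc_effect_distal != 0) {
    shifted <- matrix(FALSE, p, p)
    shifted[distal, ] <- TRUE
    shifted[, distal] <- TRUE
    diag(shifted) <- FALSE
    fc[shifted] <- fc[shifted] + fc_effect_distal
    fc <- clip_open(fc)
    diag(fc) <- 0
  }

  tumor_fraction <- rep(0, p); tumor_fraction[tumor] <- 1
  edema_fraction <- rep(0, p); edema_fraction[edema] <- 1
  record <- subject_records(tibble(
    subject_id = subject_id, cohort = "glioma", split = split,
    lesion_hemisphere = lesion_hemisphere,
    volume_T = length(tumor) * spec$volume_per_parcel,
    volume_TO = (length(tumor) + length(edema)) * spec$volume_per_parcel,
    tumor_fraction = list(tumor_fraction),
    edema_fraction = list(edema_fraction)
  ), scheme = scheme)
  ground_truth <- list(
    tumor_parcels = scheme$parcel_id[tumor],
    edema_parcels = scheme$parcel_id[edema],
    sc_perturbed = if (null_effect || sc_effect == 1) character(0)
                   else scheme$parcel_id[tumor],
    fc_perturbed = if (null_effect || fc_effect_distal == 0) character(0)
                   else scheme$parcel_id[distal],
    distal_network = distal_key
  )
  list(fc = conn_matrix(fc, "FC", subject_id),
       sc_counts = conn_matrix(sc_counts, "SC_counts", subject_id),
       record = record, ground_truth = ground_truth)
}

#' Simulate a full cohort across all splits
#'
#' Healthy subjects for the train / validation / test splits and glioma
#' subjects for fine-tuning (milder effects) and patient testing (spec
#' effects), all derived deterministically from the spec seed.
#'
#' @param spec A `connvae_sim_spec`.
#' @return List of class `connvae_sim_cohort`: `subjects` (named list with
#'   `fc`, `sc_counts`, `record`, optional `ground_truth`), `records`
#'   (combined cohort tibble), `templates`, `spec`.
#' @export
simulate_cohort <- function(spec) {
  templates <- simulate_group_template(spec)
  plan <- bind_rows(
    tibble(cohort = "healthy", split = "train", n = spec$n_train),
    tibble(cohort = "healthy", split = "validation", n = spec$n_val),
    tibble(cohort = "healthy", split = "test", n = spec$n_test),
    tibble(cohort = "glioma", split = "finetune_train",
           n = spec$n_finetune_train),
    tibble(cohort = "glioma", split = "finetune_val", n = spec$n_finetune_val),
    tibble(cohort = "glioma", split = "test", n = spec$n_patient_test)
  )
  subjects <- list()
  counter <- 0L
  for (i in seq_len(nrow(plan))) {
    for (k in seq_len(plan$n[i])) {
      counter <- counter + 1L
      sid <- sprintf("%s_%s_%02d",
                     ifelse(plan$cohort[i] == "healthy", "hc", "gl"),
                     plan$split[i], k)
      sseed <- derive_seed(spec$seed, paste0("subject_", counter))
      subjects[[sid]] <- if (plan$cohort[i] == "healthy") {
        simulate_healthy_subject(templates, spec, sseed, sid, plan$split[i])
      } else if (plan$split[i] %in% c("finetune_train", "finetune_val")) {
        simulate_glioma_subject(templates, spec, sseed, sid, plan$split[i],
                                sc_effect = spec$finetune_sc_effect,
                                fc_effect_distal = spec$finetune_fc_effect)
      } else {
        simulate_glioma_subject(templates, spec, sseed, sid, plan$split[i])
      }
    }
  }
  records <- bind_rows(lapply(subjects, `[[`, "record"))
  class(records) <- c("connvae_cohort", class(records))
  structure(list(subjects = subjects, records = records,
                 templates = templates, spec = spec),
            class = "connvae_sim_cohort")
}

#' Write a simulated cohort to disk
#'
#' Writes one FC and one SC-count matrix file per subject plus a JSON cohort
#' manifest and, when ground truth exists, a ground-truth JSON. Regenerating
#' with the same spec yields byte-identical files.
#'
#' @param cohort A `connvae_sim_cohort` (or list of subjects shaped like its
#'   `subjects` field).
#' @param out_dir Output directory (created if needed).
#' @return Path to the cohort manifest, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  subjects <- if (inherits(cohort, "connvae_sim_cohort")) cohort$subjects
              else cohort
  if (!length(subjects)) abort("empty cohort", class = "connvae_format_error")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    abort(paste("cannot create directory", out_dir), class = "connvae_io_error")
  }
  records <- list()
  truths <- list()
  for (sid in names(subjects)) {
    s <- subjects[[sid]]
    fc_path <- file.path(out_dir, paste0(sid, "_fc.tsv"))
    sc_path <- file.path(out_dir, paste0(sid, "_sc_counts.tsv"))
    write_conn_matrix(s$fc, fc_path, modality = "FC", subject_id = sid)
    write_conn_matrix(s$sc_counts, sc_path, modality = "SC_counts",
                      subject_id = sid)
    rec <- s$record
    rec$fc_path <- basename(fc_path)
    rec$sc_path <- basename(sc_path)
    records[[sid]] <- rec
    if (!is.null(s$ground_truth)) truths[[sid]] <- s$ground_truth
  }
  manifest_path <- file.path(out_dir, "cohort.json")
  write_cohort_manifest(bind_rows(records), manifest_path)
  if (length(truths)) {
    jsonlite::write_json(truths, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(manifest_path)
}
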