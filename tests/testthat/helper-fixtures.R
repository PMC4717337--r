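# Shared fixtures; expensive microclimate runs are memoised per session.

gnp_site <- pika_site()

ref_chamber <- chamber_animal()

.mc_cache <- new.env(parent = emptyenv())

cached_microclimate <- function(month = 7, warming_delta = 0,
                                shade = TRUE, wind_animal = NULL) {
  key <- paste(month, warming_delta, shade,
               ifelse(is.null(wind_animal), "sched", wind_animal),
               sep = "_")
  if (is.null(.mc_cache[[key]])) {
    w <- gnp_weather(month, warming_delta = warming_delta)
    .mc_cache[[key]] <- microclimate_day(gnp_site, w, month, shade = shade,
                                         wind_animal = wind_animal)
  }
  .mc_cache[[key]]
}

cached_budget <- function(animal, month = 7, warming_delta = 0) {
  daily_activity_budget(animal, gnp_site, month,
                        warming_delta = warming_delta,
                        microclimate = cached_microclimate(month,
                                                           warming_delta))
}

.tnz_cache <- new.env(parent = emptyenv())

cached_tnz <- function(pelage = "summer") {
  if (is.null(.tnz_cache[[pelage]]))
    .tnz_cache[[pelage]] <- thermal_neutral_zone(chamber_animal(pelage = pelage))
  .tnz_cache[[pelage]]
}
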