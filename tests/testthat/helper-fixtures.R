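# shared fixtures built in code

fa <- standard_fatty_acids()

tag <- function(...) tag_species(lapply(list(...), function(l) fa[[l]]))

# peak table with explicitly chosen areas/annotations and unit bookkeeping
flat_peak_table <- function(areas, annotations, time_point = 0,
                            is_area = 1000, m_lp = 150, m_a = 150) {
  peak_table(sample_id = "test", time_point_min = time_point,
             peaks = data.frame(retention_min = seq_along(areas),
                                area = areas, annotation = annotations),
             is_area = is_area, m_lp_mg = m_lp, m_a_mg = m_a)
}
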