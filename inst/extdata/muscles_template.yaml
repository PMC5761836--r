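# Muscle configuration template: the full adductor inventory of the
# pharyngeal jaw apparatus (seven bilateral pairs, two median muscles).
# Fill in pcsa (mm^2, from oblique-slice measurements) and point each
# insertion_set / origin_set at node sets of your labeled mesh, or give
# origin_point (mm) for origins outside the meshed structure.
# specific_tension defaults to 2.5 N mm^-2 when omitted.
muscles:
  - {name: levator_externus_4, side: left, insertion_set: insertion_levator_externus_4_left, origin_set: origin_levator_externus_4_left, pcsa: null}
  - {name: levator_externus_4, side: right, insertion_set: insertion_levator_externus_4_right, origin_set: origin_levator_externus_4_right, pcsa: null}
  - {name: levator_posterior, side: left, insertion_set: insertion_levator_posterior_left, origin_set: origin_levator_posterior_left, pcsa: null}
  - {name: levator_posterior, side: right, insertion_set: insertion_levator_posterior_right, origin_set: origin_levator_posterior_right, pcsa: null}
  - {name: retractor_dorsalis, side: left, insertion_set: insertion_retractor_dorsalis_left, origin_set: origin_retractor_dorsalis_left, pcsa: null}
  - {name: retractor_dorsalis, side: right, insertion_set: insertion_retractor_dorsalis_right, origin_set: origin_retractor_dorsalis_right, pcsa: null}
  - {name: levator_internus_medialis, side: left, insertion_set: insertion_levator_internus_medialis_left, origin_set: origin_levator_internus_medialis_left, pcsa: null}
  - {name: levator_internus_medialis, side: right, insertion_set: insertion_levator_internus_medialis_right, origin_set: origin_levator_internus_medialis_right, pcsa: null}
  - {name: levator_internus_lateralis, side: left, insertion_set: insertion_levator_internus_lateralis_left, origin_set: origin_levator_internus_lateralis_left, pcsa: null}
  - {name: levator_internus_lateralis, side: right, insertion_set: insertion_levator_internus_lateralis_right, origin_set: origin_levator_internus_lateralis_right, pcsa: null}
  - {name: obliquus_dorsalis, side: left, insertion_set: insertion_obliquus_dorsalis_left, origin_set: origin_obliquus_dorsalis_left, pcsa: null}
  - {name: obliquus_dorsalis, side: right, insertion_set: insertion_obliquus_dorsalis_right, origin_set: origin_obliquus_dorsalis_right, pcsa: null}
  - {name: transversus_dorsalis_anterior_1, side: left, insertion_set: insertion_transversus_dorsalis_anterior_1_left, origin_set: origin_transversus_dorsalis_anterior_1_left, pcsa: null}
  - {name: transversus_dorsalis_anterior_1, side: right, insertion_set: insertion_transversus_dorsalis_anterior_1_right, origin_set: origin_transversus_dorsalis_anterior_1_right, pcsa: null}
  - {name: transversus_dorsalis_anterior_2, side: median, insertion_set: insertion_transversus_dorsalis_anterior_2, origin_set: origin_transversus_dorsalis_anterior_2, pcsa: null}
  - {name: transversus_dorsalis_posterior, side: median, insertion_set: insertion_transversus_dorsalis_posterior, origin_set: origin_transversus_dorsalis_posterior, pcsa: null}
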