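# Published reference Young's moduli (kPa) for melanocyte/melanoma models.
# Sources of truth for the synthetic parameter-recovery scenes:
#   nhm_2d            - normal human melanocytes, 2D culture (~4 kPa)
#   ic8_hsr_section   - skin-reconstruct section, non-invasive IC8 cells
#   t1c3_hsr_section  - skin-reconstruct section, invasive T1C3 cells
#   ic8_t1c3_2d_ratio - IC8:T1C3 stiffness ratio in 2D culture (two-fold);
#                       absolute 2D moduli for these clones were not
#                       reported, so only the ratio is fixed here.
nhm_2d: 4.0
ic8_hsr_section: 16000.0
t1c3_hsr_section: 12000.0
ic8_t1c3_2d_ratio: 2.0
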