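[
  {"instrument": "handheld contact sensor", "model": "SPAD-502Plus (Konica Minolta)", "vi": "DI", "center1_nm": 650, "fwhm1_nm": 30, "center2_nm": 940, "fwhm2_nm": 10},
  {"instrument": "handheld contact sensor", "model": "Dualex 4 (Force-A)", "vi": "SR", "center1_nm": 710, "fwhm1_nm": null, "center2_nm": 850, "fwhm2_nm": null},
  {"instrument": "handheld remote sensor", "model": "PSR-1100F (Spectral Evolution)", "vi": "NDVI", "center1_nm": 531, "fwhm1_nm": 3, "center2_nm": 570, "fwhm2_nm": 3},
  {"instrument": "handheld remote sensor", "model": "FieldSpec 3 (ASD)", "vi": "NDVI", "center1_nm": 705, "fwhm1_nm": 3, "center2_nm": 750, "fwhm2_nm": 3},
  {"instrument": "multispectral imaging sensor", "model": "Parrot Sequoia", "vi": "NDVI", "center1_nm": 660, "fwhm1_nm": 40, "center2_nm": 790, "fwhm2_nm": 40},
  {"instrument": "multispectral imaging sensor", "model": "Micasense Altum", "vi": "NDVI", "center1_nm": 668, "fwhm1_nm": 14, "center2_nm": 717, "fwhm2_nm": 12},
  {"instrument": "hyperspectral imaging sensor", "model": "Micro-Hyperspec VNIR (Headwall)", "vi": "SR", "center1_nm": 515, "fwhm1_nm": 6.4, "center2_nm": 550, "fwhm2_nm": 6.4},
  {"instrument": "hyperspectral imaging sensor", "model": "Senop HSC-2", "vi": "NDVI", "center1_nm": 531, "fwhm1_nm": 6, "center2_nm": 570, "fwhm2_nm": 6}
]
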