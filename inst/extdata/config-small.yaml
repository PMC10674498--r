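# 560-px scaled-down preset of the default SA-DHM simulation geometry
n_pixels: 560
pixel_pitch: 1.0
wavelength: 0.532
f1: 10
f2: 200
defocus_d: 2.5
fourier_mask_diameter_px: 56
aperture_radius_px: 140
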