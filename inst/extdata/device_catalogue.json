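{
  "contour": [
    {
      "product_code": "CNS21005-15",
      "family": "contour",
      "microcatheter_id_in": 0.021,
      "nominal_diameter_mm": 5,
      "dn_range_mm": [2.0, 3.0],
      "da_range_mm": [2.0, 3.5],
      "wires_per_layer": 72,
      "layers": 2,
      "nominal_porosity": null,
      "nominal_pore_density_per_mm": null
    },
    {
      "product_code": "CNS21007-15",
      "family": "contour",
      "microcatheter_id_in": 0.021,
      "nominal_diameter_mm": 7,
      "dn_range_mm": [3.0, 5.0],
      "da_range_mm": [3.0, 5.5],
      "wires_per_layer": 72,
      "layers": 2,
      "nominal_porosity": null,
      "nominal_pore_density_per_mm": null
    },
    {
      "product_code": "CNS21009-15",
      "family": "contour",
      "microcatheter_id_in": 0.021,
      "nominal_diameter_mm": 9,
      "dn_range_mm": [4.0, 6.0],
      "da_range_mm": [5.0, 7.5],
      "wires_per_layer": 72,
      "layers": 2,
      "nominal_porosity": null,
      "nominal_pore_density_per_mm": null
    },
    {
      "product_code": "CNS011-15",
      "family": "contour",
      "microcatheter_id_in": 0.027,
      "nominal_diameter_mm": 11,
      "dn_range_mm": [5.0, 8.0],
      "da_range_mm": [7.0, 8.5],
      "wires_per_layer": 72,
      "layers": 2,
      "nominal_porosity": null,
      "nominal_pore_density_per_mm": null
    },
    {
      "product_code": "CNS014-15",
      "family": "contour",
      "microcatheter_id_in": 0.027,
      "nominal_diameter_mm": 14,
      "dn_range_mm": [7.0, 10.0],
      "da_range_mm": [8.0, 10.5],
      "wires_per_layer": 72,
      "layers": 2,
      "nominal_porosity": null,
      "nominal_pore_density_per_mm": null
    }
  ],
  "braided": [
    {
      "product_code": "SVB-2.25x15",
      "family": "braided_stent",
      "microcatheter_id_in": 0.017,
      "nominal_diameter_mm": 2.25,
      "length_mm": 15,
      "wires_per_layer": 48,
      "layers": 1,
      "nominal_porosity": 0.60,
      "nominal_pore_density_per_mm": 45
    },
    {
      "product_code": "SVB-2.5x15",
      "family": "braided_stent",
      "microcatheter_id_in": 0.017,
      "nominal_diameter_mm": 2.5,
      "length_mm": 15,
      "wires_per_layer": 48,
      "layers": 1,
      "nominal_porosity": 0.60,
      "nominal_pore_density_per_mm": 45
    },
    {
      "product_code": "SVB-2.75x15",
      "family": "braided_stent",
      "microcatheter_id_in": 0.017,
      "nominal_diameter_mm": 2.75,
      "length_mm": 15,
      "wires_per_layer": 48,
      "layers": 1,
      "nominal_porosity": 0.60,
      "nominal_pore_density_per_mm": 45
    },
    {
      "product_code": "SVB-3x15",
      "family": "braided_stent",
      "microcatheter_id_in": 0.017,
      "nominal_diameter_mm": 3,
      "length_mm": 15,
      "wires_per_layer": 48,
      "layers": 1,
      "nominal_porosity": 0.60,
      "nominal_pore_density_per_mm": 45
    },
    {
      "product_code": "SVB-3.25x15",
      "family": "braided_stent",
      "microcatheter_id_in": 0.017,
      "nominal_diameter_mm": 3.25,
      "length_mm": 15,
      "wires_per_layer": 48,
      "layers": 1,
      "nominal_porosity": 0.60,
      "nominal_pore_density_per_mm": 45
    }
  ]
}
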