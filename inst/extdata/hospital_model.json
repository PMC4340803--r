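{
  "name": "hospital",
  "enumerations": [
    {
      "name": "pCode",
      "literals": [
        "XR",
        "CT",
        "US",
        "LAB",
        "ECG"
      ]
    },
    {
      "name": "dCode",
      "literals": [
        "Chickenpox",
        "Pneumonia",
        "Stroke",
        "Influenza",
        "Appendicitis",
        "Fracture"
      ]
    }
  ],
  "activities": [
    {
      "name": "Patient enters the hospital",
      "master": true,
      "attributes": [
        {
          "name": "age",
          "type": "Integer"
        },
        {
          "name": "surname",
          "type": "String"
        }
      ]
    },
    {
      "name": "Patient admitted to hospital ward",
      "master": false,
      "attributes": []
    },
    {
      "name": "Clinical process in ward",
      "master": false,
      "attributes": [
        {
          "name": "total_expenses",
          "type": "Real"
        }
      ]
    },
    {
      "name": "Doctor assigns procedure",
      "master": false,
      "attributes": [
        {
          "name": "procedure_code",
          "type": "pCode"
        }
      ]
    },
    {
      "name": "Procedure is executed",
      "master": false,
      "attributes": [
        {
          "name": "procedure_code",
          "type": "pCode"
        },
        {
          "name": "cost",
          "type": "Real"
        }
      ]
    },
    {
      "name": "Doctor sets diagnosis",
      "master": false,
      "attributes": [
        {
          "name": "diagnosis",
          "type": "dCode"
        }
      ]
    },
    {
      "name": "Patient consulted by second doctor",
      "master": false,
      "attributes": []
    },
    {
      "name": "Patient discharged from hospital",
      "master": false,
      "attributes": []
    },
    {
      "name": "Patient transferred to another ward",
      "master": false,
      "attributes": []
    }
  ],
  "edges": [
    {
      "kind": "follows",
      "source": "Patient enters the hospital",
      "target": "Patient admitted to hospital ward"
    },
    {
      "kind": "follows",
      "source": "Patient admitted to hospital ward",
      "target": "Clinical process in ward"
    },
    {
      "kind": "composition",
      "source": "Clinical process in ward",
      "target": "Doctor assigns procedure",
      "cardinality": "*"
    },
    {
      "kind": "composition",
      "source": "Clinical process in ward",
      "target": "Doctor sets diagnosis",
      "cardinality": "*"
    },
    {
      "kind": "follows",
      "source": "Doctor assigns procedure",
      "target": "Procedure is executed"
    },
    {
      "kind": "extension",
      "source": "Doctor sets diagnosis",
      "target": "Patient consulted by second doctor",
      "extension_point": "second opinion is necessary"
    },
    {
      "kind": "interruption",
      "source": "Clinical process in ward",
      "target": "Patient discharged from hospital"
    },
    {
      "kind": "interruption",
      "source": "Clinical process in ward",
      "target": "Patient transferred to another ward"
    }
  ]
}
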