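disease,drug,probability
"Integumentory system cancer","Arcitumomab",90.52
"Hypertension","L-arginine",89.44
"Type 2 diabetes mellitus","Insulin",88.980385
"Cardiovascular system disease","Selegiline",87.93291
"Ulcerative colitis","Infliximab",87.20253
"Autonomic nervous system neoplasm","Loteprednol",87.038925
"Hematologic cancer","L-ornithine",86.95308
"Ulcerative colitis","Olsalazine",86.79947
"Vitiligo","Loteprednol",86.54014
"Crohn’s disease","Infliximab",86.485664
"Gastrointestinal system cancer","Golimumab",86.456894
"Colitis","Olsalazine",86.39726
"Colitis","Azathioprine",86.141464
"Intestinal benign neoplasm","Olsalazine",86.11937
"Inflammatory bowel disease","Hydrocortisone",86.08773
"Crohn’s disease","Olsalazine",85.965416
"Intestinal cancer","Olsalazine",85.94351
"Crohn’s disease","Balsalazide",85.63084
"Colorectal cancer","Hydrocortisone",85.55948
"Systemic scleroderma","L-arginine",85.43495
"Crohn’s disease","Certolizumab pegol",85.31858
"Gastrointestinal system disease","Balsalazide",85.06852
"Dermatitis","L-ornithine",84.991
"Gastrointestinal system disease","Certolizumab pegol",84.908
"Gastrointestinal system benign neoplasm","Balsalazide",84.827
"Crohn’s disease","Budesonide",84.744
"Muscular disease","L-ornithine",84.532
"Demyelinating disease","Tinidazole",83.901
"Demyelinating disease","Ivermectin",83.811
"Leprosy","Tetracycline",83.778
"Peripheral artery disease","Riboflavin",83.776
"Nasal disorder","Tetracycline",83.659
"Muscular disease","Adalimumab",83.642
"Reproductive organ cancer","Tetracycline",83.485
"Hematologic cancer","Nimodipine",83.203
"Autoimmune disease of the nervous system","Ivermectin",83.107
"Testicular cancer","Tinidazole",82.969
"Testicular cancer","Sulfisoxazole",82.877
"Neurodegenerative disease","Tinidazole",82.860
"Neurodegenerative disease","Tetracycline",82.828
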