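"variety","preparation","replicate","element","value","unit"
"Barone","cooked",1,"Al",0.0028,"ng/g"
"Barone","cooked",1,"Cd",1.8e-05,"ng/g"
"Barone","cooked",1,"Cr",5.2e-05,"ng/g"
"Barone","cooked",1,"Pb",1.8e-05,"ng/g"
"Barone","cooked",1,"As",3.6e-05,"ng/g"
"Basmati","cooked",1,"Al",0.0021,"ng/g"
"Basmati","cooked",1,"Cd",1.8e-05,"ng/g"
"Basmati","cooked",1,"Cr",6.1e-05,"ng/g"
"Basmati","cooked",1,"Pb",1.8e-05,"ng/g"
"Basmati","cooked",1,"As",3.2e-05,"ng/g"
"Guadiamar","cooked",1,"Al",0.0023,"ng/g"
"Guadiamar","cooked",1,"Cd",1.8e-05,"ng/g"
"Guadiamar","cooked",1,"Cr",3.2e-05,"ng/g"
"Guadiamar","cooked",1,"Pb",1.8e-05,"ng/g"
"Guadiamar","cooked",1,"As",3.6e-05,"ng/g"
"Hispamar","cooked",1,"Al",0.0022,"ng/g"
"Hispamar","cooked",1,"Cd",1.8e-05,"ng/g"
"Hispamar","cooked",1,"Cr",2.1e-05,"ng/g"
"Hispamar","cooked",1,"Pb",1.8e-05,"ng/g"
"Hispamar","cooked",1,"As",3.6e-05,"ng/g"
"Jasmine","cooked",1,"Al",0.0023,"ng/g"
"Jasmine","cooked",1,"Cd",1.8e-05,"ng/g"
"Jasmine","cooked",1,"Cr",6.5e-05,"ng/g"
"Jasmine","cooked",1,"Pb",1.8e-05,"ng/g"
"Jasmine","cooked",1,"As",3.6e-05,"ng/g"
"Marisma","cooked",1,"Al",0.0019,"ng/g"
"Marisma","cooked",1,"Cd",1.8e-05,"ng/g"
"Marisma","cooked",1,"Cr",3e-05,"ng/g"
"Marisma","cooked",1,"Pb",1.8e-05,"ng/g"
"Marisma","cooked",1,"As",3.6e-05,"ng/g"
"Memby","cooked",1,"Al",0.0019,"ng/g"
"Memby","cooked",1,"Cd",1.8e-05,"ng/g"
"Memby","cooked",1,"Cr",8.7e-06,"ng/g"
"Memby","cooked",1,"Pb",1.8e-05,"ng/g"
"Memby","cooked",1,"As",3.6e-05,"ng/g"
"Perlado","cooked",1,"Al",0.0026,"ng/g"
"Perlado","cooked",1,"Cd",1.8e-05,"ng/g"
"Perlado","cooked",1,"Cr",0.00016,"ng/g"
"Perlado","cooked",1,"Pb",1.8e-05,"ng/g"
"Perlado","cooked",1,"As",3.6e-05,"ng/g"
"Piñana","cooked",1,"Al",0.0023,"ng/g"
"Piñana","cooked",1,"Cd",1.8e-05,"ng/g"
"Piñana","cooked",1,"Cr",4.7e-05,"ng/g"
"Piñana","cooked",1,"Pb",1.8e-05,"ng/g"
"Piñana","cooked",1,"As",3.6e-05,"ng/g"
"Puntal","cooked",1,"Al",0.0031,"ng/g"
"Puntal","cooked",1,"Cd",1.8e-05,"ng/g"
"Puntal","cooked",1,"Cr",6.3e-05,"ng/g"
"Puntal","cooked",1,"Pb",1.8e-05,"ng/g"
"Puntal","cooked",1,"As",3.6e-05,"ng/g"
"Sendra","cooked",1,"Al",0.0025,"ng/g"
"Sendra","cooked",1,"Cd",1.8e-05,"ng/g"
"Sendra","cooked",1,"Cr",6e-05,"ng/g"
"Sendra","cooked",1,"Pb",1.8e-05,"ng/g"
"Sendra","cooked",1,"As",3.6e-05,"ng/g"
"Sole","cooked",1,"Al",0.0022,"ng/g"
"Sole","cooked",1,"Cd",1.8e-05,"ng/g"
"Sole","cooked",1,"Cr",6e-05,"ng/g"
"Sole","cooked",1,"Pb",1.8e-05,"ng/g"
"Sole","cooked",1,"As",3.6e-05,"ng/g"
"Sona Masoori","cooked",1,"Al",0.0023,"ng/g"
"Sona Masoori","cooked",1,"Cd",1.8e-05,"ng/g"
"Sona Masoori","cooked",1,"Cr",6.7e-05,"ng/g"
"Sona Masoori","cooked",1,"Pb",1.8e-05,"ng/g"
"Sona Masoori","cooked",1,"As",3.6e-05,"ng/g"
"Thaiperla","cooked",1,"Al",0.0024,"ng/g"
"Thaiperla","cooked",1,"Cd",1.8e-05,"ng/g"
"Thaiperla","cooked",1,"Cr",4.3e-05,"ng/g"
"Thaiperla","cooked",1,"Pb",1.8e-05,"ng/g"
"Thaiperla","cooked",1,"As",3.6e-05,"ng/g"
"Barone","digestible",1,"Al",0.0013,"ng/g"
"Barone","digestible",1,"Cd",8.6e-06,"ng/g"
"Barone","digestible",1,"Cr",1.8e-05,"ng/g"
"Barone","digestible",1,"Pb",8.6e-05,"ng/g"
"Barone","digestible",1,"As",1.7e-05,"ng/g"
"Basmati","digestible",1,"Al",0.0022,"ng/g"
"Basmati","digestible",1,"Cd",1.2e-05,"ng/g"
"Basmati","digestible",1,"Cr",1.8e-05,"ng/g"
"Basmati","digestible",1,"Pb",1.2e-05,"ng/g"
"Basmati","digestible",1,"As",2.4e-05,"ng/g"
"Guadiamar","digestible",1,"Al",0.0012,"ng/g"
"Guadiamar","digestible",1,"Cd",8.1e-06,"ng/g"
"Guadiamar","digestible",1,"Cr",1.8e-05,"ng/g"
"Guadiamar","digestible",1,"Pb",8.1e-06,"ng/g"
"Guadiamar","digestible",1,"As",1.6e-05,"ng/g"
"Hispamar","digestible",1,"Al",0.00073,"ng/g"
"Hispamar","digestible",1,"Cd",5.1e-06,"ng/g"
"Hispamar","digestible",1,"Cr",1.8e-05,"ng/g"
"Hispamar","digestible",1,"Pb",5.1e-06,"ng/g"
"Hispamar","digestible",1,"As",1e-05,"ng/g"
"Jasmine","digestible",1,"Al",0.0014,"ng/g"
"Jasmine","digestible",1,"Cd",1.1e-05,"ng/g"
"Jasmine","digestible",1,"Cr",1.8e-05,"ng/g"
"Jasmine","digestible",1,"Pb",1.1e-05,"ng/g"
"Jasmine","digestible",1,"As",2.2e-05,"ng/g"
"Marisma","digestible",1,"Al",0.0013,"ng/g"
"Marisma","digestible",1,"Cd",9e-06,"ng/g"
"Marisma","digestible",1,"Cr",1.8e-05,"ng/g"
"Marisma","digestible",1,"Pb",9e-06,"ng/g"
"Marisma","digestible",1,"As",1.8e-05,"ng/g"
"Memby","digestible",1,"Al",0.0011,"ng/g"
"Memby","digestible",1,"Cd",8.7e-06,"ng/g"
"Memby","digestible",1,"Cr",1.8e-05,"ng/g"
"Memby","digestible",1,"Pb",8.7e-06,"ng/g"
"Memby","digestible",1,"As",1.7e-05,"ng/g"
"Perlado","digestible",1,"Al",0.002,"ng/g"
"Perlado","digestible",1,"Cd",1.1e-05,"ng/g"
"Perlado","digestible",1,"Cr",1.8e-05,"ng/g"
"Perlado","digestible",1,"Pb",1.1e-05,"ng/g"
"Perlado","digestible",1,"As",2.3e-05,"ng/g"
"Piñana","digestible",1,"Al",0.0011,"ng/g"
"Piñana","digestible",1,"Cd",7.9e-06,"ng/g"
"Piñana","digestible",1,"Cr",0.00013,"ng/g"
"Piñana","digestible",1,"Pb",7.9e-06,"ng/g"
"Piñana","digestible",1,"As",1.6e-05,"ng/g"
"Puntal","digestible",1,"Al",0.0019,"ng/g"
"Puntal","digestible",1,"Cd",1.3e-05,"ng/g"
"Puntal","digestible",1,"Cr",1.8e-05,"ng/g"
"Puntal","digestible",1,"Pb",1.3e-05,"ng/g"
"Puntal","digestible",1,"As",2.5e-05,"ng/g"
"Sendra","digestible",1,"Al",0.0014,"ng/g"
"Sendra","digestible",1,"Cd",1.2e-05,"ng/g"
"Sendra","digestible",1,"Cr",1e-05,"ng/g"
"Sendra","digestible",1,"Pb",1.2e-05,"ng/g"
"Sendra","digestible",1,"As",2.4e-05,"ng/g"
"Sole","digestible",1,"Al",0.0016,"ng/g"
"Sole","digestible",1,"Cd",1.2e-05,"ng/g"
"Sole","digestible",1,"Cr",1.8e-05,"ng/g"
"Sole","digestible",1,"Pb",1.2e-05,"ng/g"
"Sole","digestible",1,"As",0.0018,"ng/g"
"Sona Masoori","digestible",1,"Al",0.0018,"ng/g"
"Sona Masoori","digestible",1,"Cd",1.3e-05,"ng/g"
"Sona Masoori","digestible",1,"Cr",1.8e-05,"ng/g"
"Sona Masoori","digestible",1,"Pb",1.3e-05,"ng/g"
"Sona Masoori","digestible",1,"As",2.7e-05,"ng/g"
"Thaiperla","digestible",1,"Al",0.002,"ng/g"
"Thaiperla","digestible",1,"Cd",8.7e-06,"ng/g"
"Thaiperla","digestible",1,"Cr",1.8e-05,"ng/g"
"Thaiperla","digestible",1,"Pb",8.7e-06,"ng/g"
"Thaiperla","digestible",1,"As",1.7e-05,"ng/g"
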