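patient_id	date	kind	detail	value	source
P000001	1943-12-09	patient	female		
P000001	2015-02-06	text		Verenpaine seurannassa, jatkot sovitusti.	structured
P000001	2018-02-27	text		Potilas voi hyvin, ei erityistä.	structured
P000001	2022-04-16	text		Potilas voi hyvin, ei erityistä. Ei käytä alkoholia.	structured
P000002	1974-03-29	patient	male		
P000002	2015-04-28	text		Potilas voi hyvin, ei erityistä.	structured
P000002	2017-07-28	measurement	fasting_glucose	4.9	structured
P000002	2021-12-05	text		Kontrollikäynti sovitusti. Vointi ennallaan.	structured
P000003	1942-12-05	patient	female		
P000003	2014-08-04	text		Kontrollikäynti sovitusti. Vointi ennallaan.	structured
P000003	2014-10-31	text		Verenpaine seurannassa, jatkot sovitusti.	structured
P000003	2017-12-06	text		Kontrollikäynti sovitusti. Vointi ennallaan. Tupakoi päivittäin noin askin.	structured
P000003	2018-09-05	text		Kontrollikäynti sovitusti. Vointi ennallaan.	structured
P000003	2019-11-14	text		Potilas voi hyvin, ei erityistä.	structured
P000004	1940-11-16	patient	female		
P000004	2015-12-23	text		Potilas voi hyvin, ei erityistä.	structured
P000004	2017-07-24	text		Verenpaine seurannassa, jatkot sovitusti. Tupakoimaton.	structured
P000004	2020-04-06	text		Potilas voi hyvin, ei erityistä.	structured
P000005	1950-11-10	patient	male		
P000005	2014-02-27	text		Potilas voi hyvin, ei erityistä.	structured
P000005	2014-08-25	text		Potilas voi hyvin, ei erityistä.	structured
P000005	2015-12-22	text		Kontrollikäynti sovitusti. Vointi ennallaan.	structured
P000005	2017-05-21	text		Verenpaine seurannassa, jatkot sovitusti.	structured
P000005	2017-09-06	diagnosis	ICPC-2	P17	structured
P000005	2019-07-16	text		Verenpaine seurannassa, jatkot sovitusti.	structured
P000005	2020-02-22	text		Potilas voi hyvin, ei erityistä. Käyttää alkoholia kohtuullisesti viikonloppuisin.	structured
P000005	2021-09-24	diagnosis	ICD-10	E11.9	structured
P000006	1958-05-16	patient	female		
P000006	2015-03-21	measurement	weight	76.7	structured
P000006	2015-04-23	text		Verenpaine seurannassa, jatkot sovitusti.	structured
P000006	2015-06-12	measurement	weight	83.1	structured
P000006	2019-08-09	text		Potilas voi hyvin, ei erityistä.	structured
P000006	2020-07-09	measurement	weight	72	structured
P000006	2021-02-08	measurement	weight	51.2	structured
P000007	1961-01-09	patient	male		
P000007	2014-01-16	diagnosis	ICD-10	E11.9	structured
P000007	2016-10-20	measurement	bmi	31	structured
P000007	2017-10-09	measurement	height	163.4	structured
P000007	2019-11-02	text		Kontrollikäynti sovitusti. Vointi ennallaan.	structured
P000007	2020-10-20	text		Potilas voi hyvin, ei erityistä. Käyttää alkoholia kohtuullisesti viikonloppuisin.	structured
P000007	2020-12-01	text		Potilas voi hyvin, ei erityistä.	structured
P000008	1945-04-24	patient	male		
P000008	2015-04-08	measurement	bmi	38.7	structured
P000008	2020-02-12	measurement	height	170.6	structured
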