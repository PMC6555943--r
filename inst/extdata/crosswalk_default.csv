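source,raw_label,factor_name,category,direction
google,bakery,Bakery,food,unclassified
google,bar,Bar,food,unclassified
google,bus_station,Bus station,transport,obesogenic
google,cafe,Cafe,food,unclassified
google,convenience_store,Convenience store,food,obesogenic
google,dentist,Dentist,doctor,unclassified
google,doctor,Doctor,doctor,protective
google,food,Food,food,obesogenic
google,grocery_or_supermarket,Grocery or supermarket,food,protective
google,gym,Gym,sport,protective
google,hospital,Hospital,doctor,unclassified
google,meal_delivery,Meal delivery,food,obesogenic
google,meal_takeaway,Meal takeaway,food,obesogenic
google,park,Park,other,protective
google,pharmacy,Pharmacy,doctor,unclassified
google,physiotherapist,Physiotherapist,doctor,unclassified
google,restaurant,Restaurant,food,protective
google,school,School,education,protective
google,spa,Spa,sport,unclassified
google,stadium,Stadium,sport,protective
google,subway_station,Subway station,transport,obesogenic
google,taxi_stand,Taxi stand,transport,obesogenic
google,train_station,Train station,transport,obesogenic
google,transit_station,Transit station,transport,obesogenic
google,university,University,education,protective
osm,amenity=bar,Bar,food,unclassified
osm,amenity=bbq,Bbq,food,unclassified
osm,amenity=biergarten,Biergarten,food,unclassified
osm,amenity=cafe,Cafe,food,unclassified
osm,amenity=fast_food,Fast food,food,obesogenic
osm,amenity=food_court,Food court,food,obesogenic
osm,amenity=ice_cream,Ice cream,food,unclassified
osm,amenity=pub,Pub,food,unclassified
osm,amenity=restaurant,Restaurant,food,protective
osm,amenity=college,College,education,protective
osm,amenity=school,School,education,protective
osm,amenity=bicycle_parking,Bicycle parking,transport,protective
osm,amenity=bicycle_rental,Bicycle rental,transport,protective
osm,amenity=boat_sharing,Boat sharing,transport,unclassified
osm,amenity=bus_station,Bus station,transport,obesogenic
osm,amenity=taxi,Taxi,transport,obesogenic
osm,amenity=clinic,Clinic,doctor,unclassified
osm,amenity=dentist,Dentist,doctor,unclassified
osm,amenity=doctors,Doctors,doctor,protective
osm,amenity=hospital,Hospital,doctor,unclassified
osm,amenity=nursing_home,Nursing home,doctor,unclassified
osm,amenity=pharmacy,Pharmacy,doctor,unclassified
osm,amenity=dive_centre,Dive centre,sport,protective
osm,amenity=dojo,Dojo,sport,protective
osm,amenity=ranger_station,Ranger station,other,unclassified
osm,amenity=beach_resort,Beach resort,other,protective
osm,amenity=dance,Dance,sport,protective
osm,amenity=fishing,Fishing,sport,protective
osm,amenity=fitness_centre,Fitness centre,sport,protective
osm,amenity=garden,Garden,other,protective
osm,amenity=golf_course,Golf course,sport,protective
osm,amenity=ice_rink,Ice rink,sport,protective
osm,amenity=nature_reserve,Nature reserve,other,protective
osm,amenity=park,Park,other,protective
osm,amenity=pitch,Pitch,sport,protective
osm,amenity=playground,Playground,sport,protective
osm,amenity=sports_centre,Sports centre,sport,protective
osm,amenity=stadium,Stadium,sport,protective
osm,amenity=swimming_area,Swimming area,sport,protective
osm,amenity=swimming_pool,Swimming pool,sport,protective
osm,amenity=track,Track,sport,protective
osm,amenity=water_park,Water park,sport,protective
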